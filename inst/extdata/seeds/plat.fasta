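>plat_1
ESSSEGQTTAREKSATDWESENNGTKQATICRTDMDGTKH
>plat_2
EKAYEKATDAFESSAQDWYSETNGGKQAYICGTDQDGTRH
>plat_3
EASYEKQTYSRGQKANDQYSETNGGFQATQCSTDRDVHNH
>plat_4
EPSYEKQTYAREHSANDWYKETRGGKIACICSRDMRGTNT
>plat_5
CKSYSKQTYAHEKSANDVESEQWGRKQATKNGTDMDNTAH
>plat_6
EESYEKQTYAREASEGDWKSENNGGKQATRCGSDMDHTKP
>plat_7
EISYEKQNYWRETSANKWISETNGGKQATICGTDMDGTNH
>plat_8
EKSYEKQTYPREKSAYDAYSEANGGKQAIICGRDTDTTKL
>plat_9
EGQYEAQTYAREKSACDWYSKTNGRKQAQIYSTDMCGTNG
>plat_10
EKSYRKQTIASEKSAADWYYETNEGKVAEHCGTDMDRTNR
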