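>mam_1
NRKTCVTQDGHRTYKGGSNTKIFRNNHRYRTRTKNAQGRA
>mam_2
NRNECGTQDGHRNYNGGSRCKNWRLNHRNRMHYKNACIRA
>mam_3
KAKTCVKTDGHRNYKGGHNCKSWRLNDRERSHYKNRCIRA
>mam_4
NAKTCVTQDEHRHYKGGSQCESWRLNHHYRSGYKGECKSA
>mam_5
NRGDCVTADGHSNYKGGSNCKSWRLNARYRSHYLNALIRA
>mam_6
NRKSCVTRDGHRNAKGGSNNKSWRVNLNYRSHYKAAEIRR
>mam_7
NQKTCVFQDGHWNYKGGSNCKSWRLNHRYDQHDENACIRL
>mam_8
GRKTCNAQDGHKNYRGGANCKSERLNHKDRSHHKNACCRA
>mam_9
NRKTQVTADGHRSYKGGSNCRSWRLNHKYFSHCKSACIDA
>mam_10
NRKTRVTQDGHRNYYHGENIKSCQEKHRYGSHYDNACIRA
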