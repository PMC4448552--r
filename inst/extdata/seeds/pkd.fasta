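>pkd_1
HTKIEEAEAICDDAWMEDFSGCTCAKGNTSSWGSATNKCP
>pkd_2
EAQKENTEAIITDALMENSTQCTNAKSRIGSWGSFENKCP
>pkd_3
EDKKEETEAKIDDVWMQDTNKCTNAKGRHGSWGSGTNKNP
>pkd_4
EEKKCLTEHIADDAWMGDTDKCSNAKQRTGSWGSATNKCP
>pkd_5
ETKTEETEAIIDDGHTEDSKECLNAKGRTGSWGSATYKCP
>pkd_6
ECKKEETEEISDCTWMEDNTKCTNASGRYGSRGSGTEKCP
>pkd_7
EGKKSMGEATIDCAWGEDGTKPTNAKGRSGSWGSEHNECP
>pkd_8
ECKKEETEAIIDDAWMENSTKCKNAKGRTGSWGHATSKCP
>pkd_9
QTSKDETEAIIDDYWMEDSYKCGNAKARTFNEGSASNKCP
>pkd_10
ETKKENSLAIIDGAWMEDSGKETNAKGRSGSDTSATNICP
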