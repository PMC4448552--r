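>srcr_1
ENCTEACARTDKNNHKNNNKQSHMSHVESTATHKRKRVTFSEVIL
>srcr_2
SGHTVACARDDKMNHKGTNDQVPMTHFDSTNTHKRARVNASCRIC
>srcr_3
EYTYPACARTDKSNHKNQTDQKGMTHYEETNTHNNKRVTFSCVTC
>srcr_4
TTHMTACARYDKSNHKGGNKQCHMTHYESTSTHYRKRVNFSAVIC
>srcr_5
CTNTCECARTDVSNHKGGNDQVQMTHYESTSNNKIKRHNDKCHGC
>srcr_6
ETRNTASARTDKSNHKGGNDQVHTTHYDSKSTHKRVRVNFSCVIC
>srcr_7
EDKTVWCARTDGSNHKGGNDQYHMTGYESTSTHKRKRVIFECGIC
>srcr_8
ETHTVACAHTDKQNNKGGNDQAHMTHYESTSTHKRKRVNFSCVIC
>srcr_9
ETHTVACGNTDKLNHKGEVCQVHMTPDVEESTHKRKRVNFSCVDC
>srcr_10
ETHTVACARCQKSADLGGNDQVNMLEDESTMTHKNKRVNFNCVIC
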