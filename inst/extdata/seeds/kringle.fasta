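>kringle_1
ICTVITSSSGNDFNGDLQHKFATNQAQCDDDRDQLDGNLS
>kringle_2
ICEVIQSESYNDDNSDLQVNYATNQARKEDGRDQLHGNKS
>kringle_3
CNEVITSMSGNDENGDHQVNFATNQASCEQGRYHLDGQKG
>kringle_4
DCEVFTSESGNDENGDLCVNFATNTASCESGRDQLDRNKS
>kringle_5
ICQVIQSSSGNDERGDLQVRFITAQRSCEDGRDKLDRNKS
>kringle_6
ICEVITLSTGSDENGDTTVNFKTNVASCEDGEASLDGSKT
>kringle_7
RCGVITSSSGNCENGDNQVNFATNQLSCEDGQDQLDGNKS
>kringle_8
CCEVFTYSGGNDTNGALEVNFATNQASNEDGRDQIDGNES
>kringle_9
ICDVEDSSEHNDENGDLQVNFATNQASCEDGRDRLDGSYS
>kringle_10
ANEVITSSSGNEKFGDYQVNSCTEQASCEEGRDQLDGNKS
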