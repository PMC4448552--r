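>lox_1
MQTGASQNRDQFKDRQIDQRGSNHGQFSCSRASNWEWHSCHQHYHSMDYSLQVWRDNHKNSHNTIDDRLKNTPGNTENTGANATYKERECVWEWTNAQTP
>lox_2
IQTGASQNRRTFSNRLIDQMGSRNSYGYRSGASEWEWHSCHQHYHSMDYRLSVWCCQHKNPHDAKFRRWKETPAQLSNLGNLATYKERECVHEHTKSQMP
>lox_3
MDTGASQNRTQFHDRGINQQGSGDSDGYRSWVSEWEWHSCHQHYHSMDYRLKTWRCNHKNNHNTIDKRWKETEQQESATGANATYKYRECAGEWTSSQMS
>lox_4
MITGHSQQRTQFSDRQIDQDGSRNSDFYGSWASTWEWHSCHQHYHSMDYRLKVWRCDHKNPHNTIDDRWKETPAQTSNIRANRTYKEREPVHEWTNSQMD
>lox_5
MQTGHPQNDTQFEKLQGDQDGSRFDDGYRSWASEWEWHSCHQHYHSMDYRSKVWRANHKNPHGTIYDRWKEQPAQTKNTGANAQYKERECVDEWTNSQMP
>lox_6
MKTGASQNRTQFRDRQIDVDGSRNADIYRSWASEWEWHSCHQHYHSMDFRQFVWRCNEKAPHNTIDDRWKKTPAQTSNTGINATYKTRECVHEWTNSQMT
>lox_7
YQTGASQNRTQEKDQQIDQNTSRVQTGYRSWANEWEWHSCHQHYHSMDYALRVYRWFQKNQQNDAQRRWKETPAQTGNTGVNATYKTSECTHEWKNSQMP
>lox_8
MQTGRNQNRTQDSDRAIDQDGSRNSDGYMSWAKEWEWHSCHQHYHSMDYRLKVWRCNHDQRTSSIDDRWKETPAQTSKTGAGATYKERSCVHKWTNSQMP
>lox_9
GFTGASDNRTQFMDYQIAQDGSRKSDGYRSWASEWEWHSCHQHYHSMDYRLYSWRCNHCAPHNTIDDRQKETPAMTSNNGANITYKERECVHEITNSQEP
>lox_10
MQTGASDGRWEFLDRQGDQYGSTGSTGYEPHTSEWEWHSCHQHYHSMDKRLHVWRCNHKNPSNTIDDRYKETTAQTSNTGANHTYKEAECVREWCNSQMP
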