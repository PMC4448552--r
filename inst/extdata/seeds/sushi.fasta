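>sushi_1
SRGSSGISCLNQLSCYTQNQGGSQTTSNINDMHIQTEDDA
>sushi_2
SRGYQGISTLNQLRCYTQNEGQSQDTSIINDMHAQTADDA
>sushi_3
SRCYSKISAQGQSSCYTQWEGQDRTTNNINDIHNQTADDA
>sushi_4
SRGYSGISALNQLYNGTQNEGQSQTTSNINDCHKQTADKA
>sushi_5
SQGYSGISALNQLSCATQLETQSYTTNSINDMHAITADPA
>sushi_6
SRGYSGQSHLNSLSCYTQNERQIGFTTSINDMHAQKARDA
>sushi_7
NDGYSGISALNTENCRTANEGQSQTTSNINDMDAQTADGA
>sushi_8
STGSSGISALNQLGCYTQYEGIHQTTSNISDMHAQTAKDA
>sushi_9
SKKYSGICATNQLSCRTDNCGDSQTTSNINDKHNDFAIEA
>sushi_10
QDGYSLISQANQLSCYTQNEGQSQTNSNINDMQAKTADDA
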