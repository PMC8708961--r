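backbone,method,tp,fp,fn,tn
cnn,supervised,147,11,309,5148
densenet121,supervised,105,20,351,5139
resnet50v2,supervised,243,27,213,5132
cnn,supcon,272,45,184,5114
densenet121,supcon,257,26,199,5133
resnet50v2,supcon,273,38,183,5121
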