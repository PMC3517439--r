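((TBel:100,(EEu:95,(BT:85,TTr:85):10):5):900,((PBa:100,HSa:100):40,SIn:140):860);
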