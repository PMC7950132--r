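>substrate1 synthetic 400-residue substrate with lysines at 45, 101, 107, 381
FCCIWWENQGSYILGNYVQCNHIYMHYCNIMCASSGYNMRGIVMKAMLCRVNDFCFMSIM
WTCWNFVWWYQNFDHTQWEGVCHLYTFMNTSGLHRTSSCGKANRTIKAIMWRYVLIGWDM
EYHESTFFSQAHAEQSHCYLQYCCMQESCDLIVGVDSWHNWMQQSQIMDIENSYEFTVCL
DIDCSDMHHYSHGTESMAFMFEFLMQCNTTNSYEFQQNNWSVETLDVEESTQCCLVSIQV
QWHNFYWCHTVNENNAEFMGHLYINDFDYCNDGHSMNFGVTNATEGEIWMGQTFMIAHII
GQQQACTTISHESQQNMFFHFFAYILYIHCDTDMIIVLVGCSWVWMHEQTEDFNCWQYTC
WLINWCYNDEWDDTRFWHHSKHLNNRLWWWEHINATVTSM
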