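>TG2_synthetic|P21980-scaffold synthetic TG2 scaffold: the seven single-lysine tryptic donor peptides at K205/K265/K429/K468/K590/K600/K677; filler regions are artificial
AGSTVLEDNHAGSVTLEDHNARSTVLEDNHAGSVTLEDHNAGSRVLEDNHAGSVTLEDHN
AGSTVREDNHAGSVTLEDHNAGSTVLERNHAGSVTLEDHNAGSTVLEDNRAGSVTLEDHN
AGSTVLEDNHARSVTLEDHNAGSTVLEDNHAGSRTLEDHNAGSTVLEDNHAGSVTREDHN
AGSTVLEDNHAGSVTLERHNARFLKNAGRAGSTVLEDNHAGSVTLEDHNARSTVLEDNHA
GSVTLEDHNAGSRVLEDNHAGSRWKNHGCQRAGSTVLEDNHAGSVTLEDHNARSTVLEDN
HAGSVTLEDHNAGSRVLEDNHAGSVTLEDHNAGSTVREDNHAGSVTLEDHNAGSTVLERN
HAGSVTLEDHNAGSTVLEDNRAGSVTLEDHNAGSTVLEDNHARSVTLEDHNAGSTVLEDN
HAGSRISTKSVGRAGSTVLEDNHAGSVTLEDHNARSTVLEDNHRLAEKEETGMAMRAGST
VLEDNHAGSVTLEDHNARSTVLEDNHAGSVTLEDHNAGSRVLEDNHAGSVTLEDHNAGST
VREDNHAGSVTLEDHNAGSTVLERNHAGSVTLEDHNAGSRDLYLENPEIKIRAGSTVRQK
RAGSTVLEDNHAGSVTLEDHNARSTVLEDNHAGSVTLEDHNAGSRVLEDNHAGSVTLEDH
NAGSTVREDNHAGRAVKGFRAGSTVLE
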