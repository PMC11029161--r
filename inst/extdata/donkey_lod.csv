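matrix,analyte,lod
plasma,ABZSO,0.01
plasma,ABZSO2,0.01
plasma,ABZSO2NH2,0.02
muscle,ABZSO,0.02
muscle,ABZSO2,0.02
muscle,ABZSO2NH2,0.02
skin,ABZSO,0.02
skin,ABZSO2,0.02
skin,ABZSO2NH2,0.02
liver,ABZSO,0.02
liver,ABZSO2,0.05
liver,ABZSO2NH2,0.02
kidney,ABZSO,0.02
kidney,ABZSO2,0.02
kidney,ABZSO2NH2,0.02
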