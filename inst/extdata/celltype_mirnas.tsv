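mirna	celltype
Mir-122_5p	hepatocyte
Mir-192_5p	epithelial
Mir-194_5p	epithelial
Mir-375_3p	epithelial
Mir-8-P1a_3p	epithelial
Mir-8-P1b_3p	epithelial
Mir-8-P2a_3p	epithelial
Mir-8-P2b_3p	epithelial
Mir-8-P3_3p	epithelial
Mir-203_3p	epithelial
Mir-205_5p	epithelial
Mir-126_3p	endothelial
Mir-126_5p	endothelial
Mir-142_3p	hematopoietic
Mir-142_5p	hematopoietic
Mir-150_5p	lymphocyte
Mir-155_5p	lymphocyte
Mir-223_3p	granulocyte
Mir-146-P1_5p	immune
Mir-146-P2_5p	immune
Mir-21_5p	immune
Mir-143_3p	mesenchymal
Mir-145_5p	mesenchymal
Mir-199-P1_5p	mesenchymal
Mir-199-P2_5p	mesenchymal
Mir-214_3p	mesenchymal
Mir-1-P1_3p	muscle
Mir-1-P2_3p	muscle
Mir-133-P1_3p	muscle
Mir-133-P2_3p	muscle
Mir-206_3p	muscle
Mir-208-P1_3p	cardiomyocyte
Mir-208-P2_3p	cardiomyocyte
Mir-9-P1_5p	neural
Mir-9-P2_5p	neural
Mir-124-P1_3p	neural
Mir-124-P2_3p	neural
Mir-128-P1_3p	neural
Mir-138-P1_5p	neural
Mir-219-P1_5p	neural
Mir-144_3p	erythrocyte
Mir-451_5p	erythrocyte
Mir-211_5p	melanocyte
Mir-204_5p	melanocyte
Mir-378_3p	adipocyte
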