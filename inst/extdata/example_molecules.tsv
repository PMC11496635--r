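formula	name	subclass	parent_class
C6H12O6	Hexose	Monosaccharides	Carbohydrates
C12H22O11	Disaccharide	Disaccharides	Carbohydrates
C6H14O6	Hexitol	Sugar alcohols	Carbohydrates
C5H10O5	Pentose	Monosaccharides	Carbohydrates
C3H7NO2	Alanine	Amino acids	Amino acids and peptides
C5H9NO4	Glutamate	Amino acids	Amino acids and peptides
C6H14N4O2	Arginine	Amino acids	Amino acids and peptides
C9H11NO2	Phenylalanine	Amino acids	Amino acids and peptides
C11H12N2O2	Tryptophan	Amino acids	Amino acids and peptides
C4H9NO3	Threonine	Amino acids	Amino acids and peptides
C16H32O2	Palmitic acid	Fatty acids	Fatty acyls
C18H34O2	Oleic acid	Fatty acids	Fatty acyls
C18H36O2	Stearic acid	Fatty acids	Fatty acyls
C20H32O2	Arachidonic acid	Fatty acids	Fatty acyls
C14H28O2	Myristic acid	Fatty acids	Fatty acyls
C40H80NO8P	PC 32:0	Glycerophosphocholines	Glycerophospholipids
C42H82NO8P	PC 34:1	Glycerophosphocholines	Glycerophospholipids
C39H76NO8P	PE 34:0	Glycerophosphoethanolamines	Glycerophospholipids
C41H78NO8P	PE 36:1	Glycerophosphoethanolamines	Glycerophospholipids
C43H81NO13P	SM-like lipid	Phosphosphingolipids	Sphingolipids
C10H16N5O13P3	ATP	Purine nucleotides	Nucleotides
C10H14N5O7P	AMP	Purine nucleotides	Nucleotides
C9H13N3O5	Cytidine	Pyrimidine nucleosides	Nucleosides
C10H12N4O5	Inosine	Purine nucleosides	Nucleosides
C7H15NO3	Carnitine	Carnitines	Fatty acyls
C9H17NO4	Acetylcarnitine	Carnitines	Fatty acyls
C4H6O4	Succinate	Dicarboxylic acids	Carboxylic acids
C6H8O7	Citrate	Tricarboxylic acids	Carboxylic acids
C4H6O5	Malate	Dicarboxylic acids	Carboxylic acids
C5H11NO2S	Methionine	Amino acids	Amino acids and peptides
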