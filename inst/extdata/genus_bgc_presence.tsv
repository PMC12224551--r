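bgc	Anaeromyxobacter	Archangium	Corallococcus	Cystobacter	Melittangium	Myxococcus	Nannocystis	Polyangium	Pyxidicoccus	Sorangium	Stigmatella
geosmin	-	+	+	+	+	+	+	+	+	+	+
carotenoid	-	+	+	+	+	+	-	+	+	+	+
VEPE/AEPE/TG-1	+	+	+	+	+	+	-	-	+	-	+
alkylpyrone	-	+	+	+	+	+	-	-	+	-	+
myxochelin	-	+	+	+	+	+	-	+	+	-	+
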