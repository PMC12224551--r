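strain	geosmin	carotenoid	VEPE/AEPE/TG-1	alkylpyrone	myxochelin
Citreicoccus inhibens	+	+	+	+	+
Hyalangium versicolor	+	+	+	+	+
Vitiosangium sp. GDMCC 1.1324	+	+	+	+	+
Chondromyces crocatus	+	+	+	+	-
Haliangium ochraceum	+	+	+	-	+
Aggregicoccus sp. 17bor-14	-	+	+	+	-
Enhygromyxa salina	+	+	-	+	-
Sandaracinus amylolyticus	-	+	-	+	+
Labilithrix luteola	-	-	+	+	-
Pseudenhygromyxa sp. WMMC2535	+	+	-	-	-
Vulgatibacter incompetus	-	-	+	+	-
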