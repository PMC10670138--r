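wordform	pos	lemma	tense
jest	verb	być	present
jestem	verb	być	present
był	verb	być	past
będzie	verb	być	future
boję	verb	bać	present
czuję	verb	czuć	present
wypadają	verb	wypadać	present
akceptuję	verb	akceptować	present
odchodzą	verb	odchodzić	present
daje	verb	dawać	present
brzydkie	adjective	brzydki	NA
suche	adjective	suchy	NA
sucha	adjective	suchy	NA
blada	adjective	blady	NA
słabe	adjective	słaby	NA
słaby	adjective	słaby	NA
zdrowe	adjective	zdrowy	NA
piękne	adjective	piękny	NA
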