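word	polarity
brzydkie	negative
brzydki	negative
suche	negative
sucha	negative
suchy	negative
blada	negative
blady	negative
słabe	negative
słaby	negative
wstyd	negative
smutek	negative
strach	negative
zdrowe	positive
zdrowy	positive
piękne	positive
piękny	positive
dobrze	positive
akceptuję	positive
wsparcie	positive
rodzina	positive
ciało	neutral
skóra	neutral
włosy	neutral
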