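{"id":"p01","text":"Moje ciało jest brzydkie i suche. Skóra blada, włosy słabe. Boję się choroby.","stage":"II","flags":{"body_image":-1,"self_esteem":-1}}
{"id":"p02","text":"Czuję się dobrze. Moje ciało jest zdrowe i piękne, akceptuję siebie.","stage":"I","flags":{"body_image":1,"self_esteem":1}}
{"id":"p03","text":"Włosy wypadają, skóra sucha, ale akceptuję swoje ciało. Rodzina daje mi wsparcie.","stage":"palliative","flags":{"body_image":2,"environment_acceptance":1}}
{"id":"p04","text":"Jestem słaby i czuję wstyd. Smutek i strach nie odchodzą.","stage":"II","flags":{"environment_acceptance":-1,"self_esteem":-1}}
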