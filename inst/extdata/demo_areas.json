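{
  "body_image": {
    "positive": ["piękne", "zdrowe", "ładne"],
    "negative": ["brzydkie", "suche", "sucha", "blada", "słabe", "wypadają"]
  },
  "environment_acceptance": {
    "positive": ["wsparcie", "rodzina", "pomoc"],
    "negative": ["samotność", "wstyd", "obcy"]
  },
  "self_esteem": {
    "positive": ["akceptuję", "wartość", "pewność"],
    "negative": ["beznadziejny", "słaby", "gorszy"]
  }
}
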