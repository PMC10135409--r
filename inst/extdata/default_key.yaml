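# Unit-weighted item -> trait scoring key (19 keyed items of 24).
# Signs: "+" scored as-is, "-" reverse-scored (x -> 8 - x).
Dominance:
  dominant: "+"
  decisive: "+"
  dependent: "-"
  fearful: "-"
  timid: "-"
Extraversion:
  sociable: "+"
  active: "+"
  solitary: "-"
  individualistic: "-"
Conscientiousness:
  predictable: "+"
  impulsive: "-"
  reckless: "-"
Agreeableness:
  sympathetic: "+"
  helpful: "+"
  gentle: "+"
Neuroticism:
  excitable: "+"
  stable: "-"
Openness:
  curious: "+"
  inventive: "+"
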