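{
  "^fig\\.? ?2 ?e": "Fig2E",
  "^s1 ?fig\\.? ?d": "S1FigD",
  "^fig\\.? ?3 ?c": "Fig3C",
  "^fig\\.? ?5 ?c": "Fig5C",
  "^fig\\.? ?5 ?f": "Fig5F",
  "^fig\\.? ?6 ?c": "Fig6C",
  "^fig\\.? ?7 ?c": "Fig7C",
  "^fig\\.? ?9 ?b": "Fig9B",
  "^s3 ?fig\\.? ?a?b?$": "S3FigAB",
  "^s3 ?fig\\.? ?c": "S3FigC"
}
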