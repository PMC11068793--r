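# Definitions

Common periodontal terms and abbreviations used throughout the package
(surfaced by `define_term()` and the `define` CLI subcommand).

- **CAL (clinical attachment loss)**: distance from the cemento-enamel
  junction to the base of the pocket; computed as probing depth plus signed
  recession.
- **PD (probing depth)**: distance from the gingival margin to the base of
  the pocket, in millimetres.
- **Recession**: position of the gingival margin relative to the CEJ;
  positive when the margin lies apical to the CEJ, negative when coronal.
- **BOP (bleeding on probing)**: site-level bleeding indicator; its fraction
  over probed sites drives the gingival-status rules.
- **Staging (I-IV)**: severity and complexity tier of periodontitis.
  Severity derives from interdental CAL (1-2 mm stage I, 3-4 mm stage II,
  5 mm or more stage III/IV); probing depths of 6 mm or more, furcation
  class II/III or vertical defects raise the stage; tooth loss and
  masticatory dysfunction distinguish stage IV from III.
- **Grading (A-C)**: progression-rate tier. Indirect evidence is percent
  radiographic bone loss divided by age; smoking and diabetes upgrade the
  grade and never lower it.
- **Extent**: localized (under 30% of teeth affected), generalized (30% or
  more), or molar-incisor pattern (only first/second molars and incisors
  affected, at least one of each).
- **Intact periodontium**: no attachment loss, no radiographic bone loss,
  no periodontal history.
- **Reduced periodontium**: attachment or bone loss present (or a treated
  history) without currently meeting the periodontitis case definition.
- **Gingivitis**: bleeding on probing at 10% or more of sites without
  meeting the periodontitis case definition.
- **Peri-implant mucositis**: bleeding or suppuration around an implant
  without progressive crestal bone loss.
- **Peri-implantitis**: progressive crestal bone loss around an implant,
  with or without bleeding.
- **Endodontic-periodontal lesion**: combined pulpal and periodontal
  pathology on a single tooth.
- **Furcation involvement**: horizontal attachment loss between the roots
  of a multirooted tooth, classes I-III.
- **Fremitus**: palpable vibration of a tooth under occlusal function, a
  sign of traumatic occlusal force.
- **Diagnosis incident**: one gold-standard secondary condition on one
  patient; a patient can contribute several incidents.
- **Gold standard**: the calibrated faculty diagnosis against which student
  and engine outputs are scored.
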