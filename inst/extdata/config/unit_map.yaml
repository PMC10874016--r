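# Canonical uptake-unit designations and observed spellings.
# relative: true marks units that express uptake relative to a control and
# cannot serve as absolute quantitative targets.
units:
  - canonical: MFI
    relative: false
    synonyms: ["mfi", "mean fluorescence intensity", "geometric mean fluorescence intensity", "gMFI"]
  - canonical: fluorescence-au
    relative: false
    synonyms: ["a.u.", "au", "AU", "arbitrary units", "fluorescence intensity (a.u.)"]
  - canonical: pmol
    relative: false
    synonyms: ["picomole", "pmoles"]
  - canonical: nmol-per-mg-protein
    relative: false
    synonyms: ["nmol/mg protein", "nmol/mg"]
  - canonical: molecules-per-cell
    relative: false
    synonyms: ["molecules/cell", "peptides per cell"]
  - canonical: percent-of-control
    relative: true
    synonyms: ["%", "percent", "percentage", "% of control"]
  - canonical: fold-change
    relative: true
    synonyms: ["fold", "fold change", "x-fold"]
  - canonical: relative-uptake
    relative: true
    synonyms: ["relative", "relative fluorescence", "RFU relative"]
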