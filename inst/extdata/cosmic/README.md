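# Public reference signature sets (not redistributed)

The comparison checks against the published separation statistics need
two public signature CSVs that are not shipped with this package. Place
them in this directory, converted to the package's signature-CSV layout
(first column `MutationType` with the 96 trinucleotide classes in
canonical order, one column per signature):

1. `cosmic_v2_signatures.csv` — the 30 legacy signature profiles
   (`Signature 1` ... `Signature 30`) from
   https://cancer.sanger.ac.uk/cosmic/signatures_v2

2. `cosmic_v3_sbs_signatures.csv` — the current SBS signature profiles
   (`SBS1`, `SBS2`, ...) from https://cancer.sanger.ac.uk/signatures/sbs/

`read_signatures_csv()` reads either file; column order is free. Without
these files the corresponding acceptance test reports the missing input.
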