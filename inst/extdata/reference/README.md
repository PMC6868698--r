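# Reference benchmark deposits

The two gold-standard drug–disease association benchmarks (the 593-drug /
313-disease set with 1933 associations and the 663 / 409 set with 2532) are
distributed by their authors and are not bundled here.

To run the reference ingestion check, download the deposit and save the two
association matrices in the canonical layout as:

    fdataset.tsv
    cdataset.tsv

in this directory, then reinstall the package. Canonical layout: TSV, first
row = drug identifiers, first column = disease identifiers, body cells 0/1
(diseases on the rows). If a deposit stores drugs on the rows, read it with
`read_association_matrix(path, transpose = TRUE)` and rewrite it with
`write_association_matrix()`.
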