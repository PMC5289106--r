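Drop-in location for the published supplementary dataset used by the
parity checks in tests/testthat/test-acceptance.R (not redistributable
with the package):

  inst/extdata/paper-supplementary/
    cpDNA.fasta   concatenated chloroplast alignment, 1948 bp, 80 sequences
                  (78 ingroup + outgroups BOL48535, BOL60966)
    ITS.fasta     ITS alignment, 666 bp, IUPAC 2ISP codes
    ncpGS.fasta   ncpGS alignment, 1089 bp
    samples.tsv   sample_id, group, lat, lon, role

Without these files the parity test block reports the directory as
missing; all other tests are self-contained (fixtures are simulated in
code).
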