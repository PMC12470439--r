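#!/usr/bin/env Rscript
# Step 1: simulate the evolutionary history of a duplicated X-linked gene
# family across four sibling species: a conserved parental copy, an early
# duplicate shared by all species, and a recent tandem cluster amplified in
# one lineage and homogenized by gene conversion. Writes the CDS set, the
# protein set, and the truth table used by the later steps.

library(dupscan)

dir.create("results", showWarnings = FALSE)

SEED <- 20260901

# Four ingroup species plus an outgroup; branch lengths in subs/site.
TREE <- paste0("((mel:0.030,(sim:0.012,(mau:0.008,sec:0.008):0.004):0.018)",
               ":0.020,yak:0.060);")

fam <- evolve_family(list(
  tree = TREE,
  n_codons = 250,
  omega = 0.15,            # the family is broadly conserved
  kappa = 2,
  seed = SEED,
  # an early duplication shared by the melanogaster-like clade, then a
  # recent 5-copy tandem amplification in one lineage, conversion-homogenized
  duplications = data.frame(
    branch = c("n2", "mel"),
    count = c(1, 5),
    destination = c("adjacent", "cluster")),
  conversion_rate = 0.8))

write_fasta(fam$sequences, "results/family_cds.fasta")
prot <- vapply(fam$sequences, translate_cds, character(1))
write_fasta(prot, "results/family_protein.fasta")
write.table(fam$truth, "results/family_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_copies <- table(fam$truth$tip)
cat("Simulated", length(fam$sequences), "gene copies across",
    length(n_copies), "species:\n")
print(n_copies)
cat("Cluster copies in 'mel':", sum(fam$truth$cluster & fam$truth$tip == "mel"),
    "(conversion-homogenized)\n")
cat("Wrote results/family_cds.fasta, results/family_protein.fasta,",
    "results/family_truth.tsv\n")
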