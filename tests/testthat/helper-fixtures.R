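# Small hand-built fixtures shared across test files.

# 3 individuals x 2 SNP markers, fully called
tiny_gm <- function() {
  geno_matrix(
    markers = data.frame(id = c("m1", "m2"), scaffold = c("sc1", "sc1"),
                         position = c(100L, 500L), kind = "SNP"),
    individuals = c("i1", "i2", "i3"),
    a1 = matrix(c("A", "A", "C", "G", "G", "T"), 3, 2),
    a2 = matrix(c("C", "A", "C", "G", "T", "T"), 3, 2),
    depth = matrix(20L, 3, 2))
}

# one family: sire A/B x dam C/C at marker "mk"; n_m sons carrying sire
# allele "A", n_f daughters carrying "B"; flips swap the sex labels of the
# first `flip` sons to create genotype-phenotype mismatches
cross_gm <- function(n_m = 8, n_f = 8, flip = 0) {
  off_id <- sprintf("o%02d", seq_len(n_m + n_f))
  sex <- rep(c("M", "F"), c(n_m, n_f))
  if (flip > 0) sex[seq_len(flip)] <- "F"
  tr <- rep(c("A", "B"), c(n_m, n_f))
  gm <- geno_matrix(
    markers = data.frame(id = "mk", scaffold = "sc1", position = 0L,
                         kind = "SSR"),
    individuals = c("sire", "dam", off_id),
    a1 = matrix(c("A", "C", tr), ncol = 1),
    a2 = matrix(c("B", "C", rep("C", n_m + n_f)), ncol = 1))
  fam <- family_ped("famX", "sire", "dam", data.frame(id = off_id, sex = sex))
  list(gm = gm, family = fam)
}

# pedigree TSV text for one family of 12 M + 12 F
ped_text_24 <- function(order_shuffled = FALSE) {
  rows <- c("fam1\tsire1\tsire\tNA",
            "fam1\tdam1\tdam\tNA",
            sprintf("fam1\to%02d\toffspring\t%s", 1:24,
                    rep(c("M", "F"), each = 12)))
  if (order_shuffled) rows <- rev(rows)
  c("family_id\tindividual_id\trole\tsex", rows)
}

two_lg_layout <- function() {
  genome_layout(data.frame(lg = c("LG5", "LG13"),
                           length_bp = c(38e6, 34e6),
                           length_morgans = c(0.9, 0.8)))
}
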