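# Shared fixtures and independent oracles for the test suite.

# quick track constructor
make_track <- function(positions, weights, L = max(positions),
                       group = "interaction", id = "T1", iso = "ISO1.1",
                       ligand = if (group == "interaction") "LIG" else NULL) {
  functional_track(track_id = id, isoform_id = iso, group = group,
                   positions = positions, weights = weights,
                   protein_length = L, ligand = ligand)
}

make_mutations <- function(positions, f = 1, iso = "ISO1.1", gene = "G1",
                           class = "missense") {
  n <- length(positions)
  data.frame(gene = rep_len(gene, n), isoform = rep_len(iso, n),
             protein_position = positions,
             mutation_class = rep_len(class, n), f = rep_len(f, n),
             sample_id = rep_len("S1", n), cancer_type = rep_len("PANCAN", n),
             stringsAsFactors = FALSE)
}

# Independent codon-mutability oracle: enumerates the nine substitutions with
# seqinr's genetic code (a code path disjoint from the implementation's).
oracle_codon_lambda <- function(codon, b) {
  translate1 <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
  aa <- translate1(codon)
  ref <- strsplit(codon, "")[[1]]
  lam <- 0
  for (d in 1:3) {
    cnt <- 0
    for (u in setdiff(c("A", "C", "G", "T"), ref[d])) {
      mut <- ref; mut[d] <- u
      maa <- translate1(paste(mut, collapse = ""))
      if (maa != "*" && maa != aa) cnt <- cnt + 1
    }
    lam <- lam + ifelse(ref[d] %in% c("A", "T"), 1, b) * cnt
  }
  lam
}

# Independent Jensen-Shannon routine (plain base-2 formula, no shortcuts)
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  unname(kl(p, m) / 2 + kl(q, m) / 2)
}

int_tracks <- function(weights, L = 20L, positions = seq_along(weights)) {
  list(make_track(positions, weights, L = L, id = "FAMI|1|LIG"))
}

# AUROC by the rank-sum formula
auroc <- function(score, label) {
  r <- rank(score)
  np <- sum(label); nn <- sum(!label)
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}
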