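# shared fixtures and independent oracles (kept deliberately naive)

random_alignment <- function(n, L, seed) {
  set.seed(seed)
  dna_alignment(setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)),
    paste0("s", seq_len(n))))
}

write_temp_fasta <- function(records, wrap = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (nm in names(records)) {
    s <- records[[nm]]
    if (!is.null(wrap)) {
      s <- substring(s, seq(1, nchar(s), wrap),
                     pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    }
    lines <- c(lines, paste0(">", nm), s)
  }
  writeLines(lines, path)
  path
}

# literal transcription of the published TN93 closed form for one pair,
# with base frequencies supplied by the caller
tn93_pair_oracle <- function(s1, s2, freqs) {
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  s1 <- s1[ok]; s2 <- s2[ok]
  L <- length(s1)
  diff <- s1 != s2
  ts_ag <- mean(diff & ((s1 == "A" & s2 == "G") | (s1 == "G" & s2 == "A")))
  ts_ct <- mean(diff & ((s1 == "C" & s2 == "T") | (s1 == "T" & s2 == "C")))
  q <- mean(diff) - ts_ag - ts_ct
  pA <- freqs[["A"]]; pC <- freqs[["C"]]; pG <- freqs[["G"]]; pT <- freqs[["T"]]
  pR <- pA + pG; pY <- pC + pT
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pC * pT / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY)
  -k1 * log(1 - ts_ag / k1 - q / (2 * pR)) -
    k2 * log(1 - ts_ct / k2 - q / (2 * pY)) -
    k3 * log(1 - q / (2 * pR * pY))
}

# spreadsheet-style re-transcription of the Tajima constants and statistic
tajima_oracle <- function(n, S, k_bar) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force empty-circumcircle test for a candidate triangle
circumcircle_empty <- function(tri, x, y) {
  ax <- x[tri[1]]; ay <- y[tri[1]]
  bx <- x[tri[2]]; by <- y[tri[2]]
  cx <- x[tri[3]]; cy <- y[tri[3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  others <- setdiff(seq_along(x), tri)
  all((x[others] - ux)^2 + (y[others] - uy)^2 >= r2 * (1 - 1e-9))
}

# star topology: one centre and `k` leaves each one step away at distinct sites
star_haplotype_table <- function(k = 10, centre_count = 20, L = 40) {
  centre <- rep("A", L)
  seqs <- c(paste(centre, collapse = ""))
  for (i in seq_len(k)) {
    v <- centre; v[i] <- "C"
    seqs <- c(seqs, paste(v, collapse = ""))
  }
  ids <- c(paste0("c", seq_len(centre_count)), paste0("l", seq_len(k)))
  aln <- dna_alignment(setNames(c(rep(seqs[1], centre_count), seqs[-1]), ids))
  collapse_haplotypes(aln)
}

study_truth <- function() {
  two_epoch_model(N1 = 1e-2, r = 5e3, N0 = 2e-3, t_trans = 4.7e-4)
}

study_priors <- function() {
  list(N0 = prior_one_over_x(1e-5, 0.1),
       N1 = prior_one_over_x(1e-5, 0.5),
       r = prior_uniform(10, 2e4),
       t_trans = prior_uniform(1e-5, 2e-3))
}
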