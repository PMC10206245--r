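# Independent oracles used across the suite. Deliberately written as slow,
# direct transcriptions (loops, enumerations) so they share no code path
# with the package implementations they check.

# exhaustive triple-loop PCIT: for every unordered trio compute the three
# first-order partials, the mean-ratio tolerance, and eliminate dominated
# edges
pcit_bruteforce <- function(r) {
  n <- nrow(r)
  elim <- matrix(FALSE, n, n)
  if (n >= 3) {
    for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
      rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
      if (abs(rxy) >= 1 || abs(rxz) >= 1 || abs(ryz) >= 1) next
      pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      eps <- mean(c(if (rxy != 0) abs(pxy / rxy) else 0,
                    if (rxz != 0) abs(pxz / rxz) else 0,
                    if (ryz != 0) abs(pyz / ryz) else 0))
      if (abs(rxy) < eps * abs(rxz) && abs(rxy) < eps * abs(ryz))
        elim[x, y] <- elim[y, x] <- TRUE
      if (abs(rxz) < eps * abs(rxy) && abs(rxz) < eps * abs(ryz))
        elim[x, z] <- elim[z, x] <- TRUE
      if (abs(ryz) < eps * abs(rxy) && abs(ryz) < eps * abs(rxz))
        elim[y, z] <- elim[z, y] <- TRUE
    }
  }
  sig <- !elim
  diag(sig) <- FALSE
  sig
}

# random correlation matrix from random data (always a valid correlation)
random_corr <- function(n_feat, n_samp, seed) {
  set.seed(seed)
  cor(matrix(rnorm(n_feat * n_samp), n_samp, n_feat))
}

rc_oracle <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# sliding-window seed-site oracle: test all four class predicates at every
# offset, report the best class per seed-match locus
scan_oracle <- function(mirna, utr) {
  mirna <- chartr("Tt", "Uu", toupper(mirna)); mirna <- toupper(mirna)
  utr <- chartr("T", "U", toupper(utr))
  seed_rc <- rc_oracle(substr(mirna, 2, 7))
  m8_rc <- rc_oracle(substr(mirna, 8, 8))
  n <- nchar(utr)
  hits <- NULL
  for (p in 1:(n - 5)) {
    if (substr(utr, p, p + 5) != seed_rc) next
    m8 <- p > 1 && substr(utr, p - 1, p - 1) == m8_rc
    a1 <- p + 6 <= n && substr(utr, p + 6, p + 6) == "A"
    row <- if (m8 && a1) c("8mer", p - 1, p + 6)
      else if (m8) c("7mer-m8", p - 1, p + 5)
      else if (a1) c("7mer-A1", p, p + 6)
      else c("6mer", p, p + 5)
    hits <- rbind(hits, row)
  }
  if (is.null(hits))
    return(data.frame(site_type = character(), utr_start = integer(),
                      utr_end = integer()))
  data.frame(site_type = hits[, 1], utr_start = as.integer(hits[, 2]),
             utr_end = as.integer(hits[, 3]), row.names = NULL)
}

# partial correlation r_xy.z via inversion of the 3x3 correlation matrix
partial_by_inversion <- function(r3) {
  p <- solve(r3)
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# exact upper-tail hypergeometric by term-by-term enumeration
hyper_tail_oracle <- function(overlap, term_size, universe_size, query_size) {
  j <- overlap:min(term_size, query_size)
  sum(choose(term_size, j) * choose(universe_size - term_size, query_size - j)) /
    choose(universe_size, query_size)
}

# hand-coded Holm step-down
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# sum of stack energies + initiation for a perfectly complementary duplex,
# read directly from the shipped parameter file (independent of the DP)
stack_sum_oracle <- function(mirna) {
  path <- system.file("extdata", "duplex_energy_params.txt", package = "mirewire")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  init <- as.numeric(tok[[which(sapply(tok, `[`, 1) == "init")]][2])
  stacks <- Filter(function(t) t[1] == "stack", tok)
  lookup <- setNames(vapply(stacks, function(t) as.numeric(t[4]), 0),
                     vapply(stacks, function(t) paste(t[2], t[3]), ""))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  b <- strsplit(toupper(mirna), "")[[1]]
  e <- init
  for (i in seq_len(length(b) - 1)) {
    p1 <- paste0(b[i], comp[b[i]])
    p2 <- paste0(b[i + 1], comp[b[i + 1]])
    e <- e + lookup[[paste(p1, p2)]]
  }
  e
}

# small random count_matrix for QC/DE tests
random_count_matrix <- function(n_feat, n_fh, n_sfh, seed, mu_log = 4,
                                kind = "miRNA") {
  set.seed(seed)
  n <- n_fh + n_sfh
  mu <- exp(rnorm(n_feat, mu_log, 1.5))
  sf <- exp(rnorm(n, 0, 0.2))
  counts <- matrix(rnbinom(n_feat * n, mu = outer(mu, sf), size = 10),
                   n_feat,
                   dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                   c(sprintf("FH%d", seq_len(n_fh)),
                                     sprintf("SFH%d", seq_len(n_sfh)))))
  count_matrix(counts, rep(c("FH", "SFH"), c(n_fh, n_sfh)), kind = kind)
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
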