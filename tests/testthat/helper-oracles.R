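# Independent brute-force oracles. These deliberately share no code with
# the package internals: pairwise statistics enumerate strain pairs
# explicitly, codon statistics re-derive everything from the genetic code
# table, and the Fisher p value is an exhaustive hypergeometric tail sum.

.oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(.oracle_code) <- names(Biostrings::GENETIC_CODE)

# pi by explicit enumeration of all strain pairs, per site, on the
# non-missing calls.
oracle_pi <- function(geno) {
  total <- 0
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    g <- g[!is.na(g)]
    if (length(g) < 2) next
    np <- 0L; nd <- 0L
    for (i in seq_len(length(g) - 1)) {
      for (j in (i + 1):length(g)) {
        np <- np + 1L
        if (g[i] != g[j]) nd <- nd + 1L
      }
    }
    total <- total + nd / np
  }
  total
}

oracle_seg_sites <- function(geno) {
  seg <- 0L
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    g <- g[!is.na(g)]
    if (length(g) >= 2 && length(unique(g)) == 2) seg <- seg + 1L
  }
  seg
}

.oracle_n_eff <- function(geno) {
  ns <- c()
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    g <- g[!is.na(g)]
    if (length(g) >= 2 && length(unique(g)) == 2) ns <- c(ns, length(g))
  }
  if (!length(ns)) return(NA_real_)
  stats::median(ns)
}

# Tajima (1989) estimator evaluated constant by constant.
oracle_tajima <- function(geno) {
  S <- oracle_seg_sites(geno)
  if (S < 1) return(NA_real_)
  n <- .oracle_n_eff(geno)
  if (is.na(n) || n < 4) return(NA_real_)
  k_hat <- oracle_pi(geno)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D* and F*, without outgroup, Simonsen-corrected
# variances, evaluated from first principles.
oracle_fu_li <- function(geno) {
  S <- oracle_seg_sites(geno)
  if (S < 1) return(c(dstar = NA_real_, fstar = NA_real_))
  n <- .oracle_n_eff(geno)
  if (is.na(n) || n < 4) return(c(dstar = NA_real_, fstar = NA_real_))
  eta_s <- 0L
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    g <- g[!is.na(g)]
    if (length(g) >= 2 && length(unique(g)) == 2) {
      if (min(sum(g == 0), sum(g == 1)) == 1) eta_s <- eta_s + 1L
    }
  }
  pi_hat <- oracle_pi(geno)
  a <- 0; b <- 0
  for (i in 1:(n - 1)) { a <- a + 1 / i; b <- b + 1 / i^2 }
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / a - vF
  c(dstar = ((n / (n - 1)) * S - a * eta_s) / sqrt(uD * S + vD * S^2),
    fstar = (pi_hat - ((n - 1) / n) * eta_s) / sqrt(uF * S + vF * S^2))
}

# Wall's B and Q by explicit set-partition comparison of adjacent
# segregating sites.
oracle_wall <- function(geno) {
  seg <- c()
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    g <- g[!is.na(g)]
    if (length(g) >= 2 && length(unique(g)) == 2) seg <- c(seg, s)
  }
  S <- length(seg)
  if (S < 2) return(c(wall_b = NA_real_, wall_q = NA_real_))
  part_of <- function(g, idx) {
    grp0 <- idx[g[idx] == g[idx[1]]]
    grp1 <- setdiff(idx, grp0)
    paste(paste(sort(grp0), collapse = ","),
          paste(sort(grp1), collapse = ","), sep = "|")
  }
  congruent <- 0L
  types <- character(0)
  for (m in seq_len(S - 1)) {
    gi <- geno[seg[m], ]; gj <- geno[seg[m + 1], ]
    idx <- which(!is.na(gi) & !is.na(gj))
    if (length(idx) < 2) next
    if (length(unique(gi[idx])) < 2 || length(unique(gj[idx])) < 2) next
    p1 <- part_of(gi, idx)
    p2 <- part_of(gj, idx)
    # canonical: order the two groups
    canon <- function(p) paste(sort(strsplit(p, "\\|")[[1]]), collapse = "|")
    if (canon(p1) == canon(p2)) {
      congruent <- congruent + 1L
      types <- c(types, canon(p1))
    }
  }
  c(wall_b = congruent / (S - 1),
    wall_q = (congruent + length(unique(types))) / S)
}

# NG86 site and difference counts by recursive pathway enumeration.
oracle_ng86 <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2))
  tr <- function(cod) .oracle_code[[cod]]
  syn_sites <- function(seq) {
    total <- 0
    for (st in seq(1, nchar(seq), 3)) {
      cod <- substr(seq, st, st + 2)
      for (p in 1:3) {
        orig <- substr(cod, p, p)
        for (bb in setdiff(c("A", "C", "G", "T"), orig)) {
          mut <- cod
          substr(mut, p, p) <- bb
          if (tr(mut) == tr(cod)) total <- total + 1 / 3
        }
      }
    }
    total
  }
  paths <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(list())
    rec <- function(cur, remaining) {
      if (!length(remaining)) return(list(list(sd = 0, nd = 0, blocked = FALSE)))
      out <- list()
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        step_syn <- tr(cur) == tr(nxt) && tr(nxt) != "*"
        hits_stop <- tr(nxt) == "*" && nxt != c2
        for (tail in rec(nxt, setdiff(remaining, p))) {
          out[[length(out) + 1]] <- list(
            sd = tail$sd + as.integer(step_syn),
            nd = tail$nd + as.integer(!step_syn),
            blocked = tail$blocked || hits_stop)
        }
      }
      out
    }
    rec(c1, dp)
  }
  Sd <- 0; Nd <- 0
  for (st in seq(1, nchar(seq1), 3)) {
    c1 <- substr(seq1, st, st + 2)
    c2 <- substr(seq2, st, st + 2)
    pp <- paths(c1, c2)
    if (!length(pp)) next
    ok <- Filter(function(p) !p$blocked, pp)
    if (!length(ok)) ok <- pp
    Sd <- Sd + mean(vapply(ok, `[[`, 0, "sd"))
    Nd <- Nd + mean(vapply(ok, `[[`, 0, "nd"))
  }
  S_sites <- (syn_sites(seq1) + syn_sites(seq2)) / 2
  N_sites <- nchar(seq1) - S_sites
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(Nd / N_sites), Ks = jc(Sd / S_sites),
       S_sites = S_sites, N_sites = N_sites, S_diff = Sd, N_diff = Nd)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins.
oracle_fisher_p <- function(Dn, Ds, Pn, Ps) {
  rowD <- Dn + Ds; rowP <- Pn + Ps; colN <- Dn + Pn
  if (rowD == 0 || rowP == 0 || colN == 0 || Ds + Ps == 0) return(1)
  lo <- max(0, colN - rowP)
  hi <- min(colN, rowD)
  probs <- stats::dhyper(lo:hi, rowD, rowP, colN)
  obs <- stats::dhyper(Dn, rowD, rowP, colN)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
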