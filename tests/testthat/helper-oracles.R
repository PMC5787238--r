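# Independent oracles used to freeze expected values.  These deliberately
# re-derive results by brute force / enumeration, without calling the code
# paths they check.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive per-character primer mismatch count
oracle_mismatches <- function(primer, window) {
  pc <- strsplit(primer, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(pc),
             function(i) !(wc[i] %in% .oracle_iupac[[pc[i]]]), logical(1)))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# exhaustive window scan for the best forward site, then the best reverse
# site strictly downstream of the forward primer; mirrors the amplification
# definition but through naive substring loops
oracle_amplicon <- function(seq, fwd, rev, max_mm = 2L) {
  S <- nchar(seq); Pf <- nchar(fwd)
  rc <- oracle_revcomp(rev); Pr <- nchar(rc)
  best_f <- NULL; best_fmm <- Inf
  for (s in seq_len(S - Pf + 1L)) {
    mm <- oracle_mismatches(fwd, substr(seq, s, s + Pf - 1L))
    if (mm < best_fmm) { best_fmm <- mm; best_f <- s }
  }
  if (is.null(best_f)) return(list(amplified = FALSE))
  amp_start <- best_f + Pf
  best_r <- NULL; best_rmm <- Inf
  s <- amp_start
  while (s + Pr - 1L <= S) {
    mm <- oracle_mismatches(rc, substr(seq, s, s + Pr - 1L))
    if (mm < best_rmm) { best_rmm <- mm; best_r <- s }
    s <- s + 1L
  }
  if (is.null(best_r)) return(list(amplified = FALSE, fwd_mm = best_fmm))
  list(
    amplified = best_fmm <= max_mm && best_rmm <= max_mm && best_r > amp_start,
    start = amp_start - 1L, end = best_r - 1L,
    fwd_mm = best_fmm, rev_mm = best_rmm
  )
}

# dense grid search over the probability simplex for the EM oracle:
# maximum of sum_i c_i log((Q pi)_i), coarse pass at `step` followed by
# nested refinement passes around the incumbent down to `final_step`
oracle_grid_loglik <- function(Q, counts, step = 1e-3, final_step = step) {
  Q <- as.matrix(Q)
  J <- ncol(Q)
  stopifnot(J <= 3L)
  eval_grid <- function(grid) {
    grid <- grid[rowSums(grid < -1e-15) == 0, , drop = FALSE]
    grid[grid < 0] <- 0
    P <- Q %*% t(grid)
    P[P <= 0] <- NA
    ll <- colSums(counts * log(P))
    k <- which.max(ll)
    list(ll = ll[k], pi = grid[k, ])
  }
  make_grid <- function(center, half_width, st) {
    if (J == 1L) return(matrix(1, 1, 1))
    a <- seq(max(0, center[1] - half_width),
             min(1, center[1] + half_width), by = st)
    if (J == 2L) return(cbind(a, 1 - a))
    b <- seq(max(0, center[2] - half_width),
             min(1, center[2] + half_width), by = st)
    ab <- expand.grid(a = a, b = b)
    ab <- ab[ab$a + ab$b <= 1 + 1e-12, ]
    cbind(ab$a, ab$b, pmax(0, 1 - ab$a - ab$b))
  }
  best <- eval_grid(make_grid(rep(1 / J, J), 1, step))
  st <- step
  while (st > final_step) {
    st_new <- st / 10
    best2 <- eval_grid(make_grid(best$pi, st, st_new))
    if (best2$ll > best$ll) best <- best2
    st <- st_new
  }
  best$ll
}

# random sequence helper
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# plant n substitutions into a sequence at given positions
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
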