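# Independent brute-force oracle: enumerate every alignment path of a profile
# HMM against a sequence and return the log2-odds of each path. Written
# directly from the model definition, independently of the package's dynamic
# programming kernels.

AA20_ORACLE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_encode <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], AA20_ORACLE)
  x[is.na(x)] <- 21L
  x
}

# all path log2-odds scores; mode "glocal" (whole sequence) or "local"
# (uniform fragment entry/exit, flanks free)
enumerate_path_scores <- function(hmm, seq, mode) {
  idx <- oracle_encode(seq)
  n <- length(idx)
  L <- hmm$L
  lM <- cbind(log2(sweep(hmm$match_emissions, 2, hmm$null_model, "/")), 0)
  lI <- cbind(log2(sweep(hmm$insert_emissions, 2, hmm$null_model, "/")), 0)
  lt <- log2(hmm$transitions)  # row r = transitions out of node r-1
  scores <- c()

  if (mode == "glocal") {
    rec <- function(state, k, pos, acc) {
      if (state == "M" || state == "D") {
        if (k == L && is.finite(lt[L + 1, paste0(state, "M")]) && pos == n) {
          scores[[length(scores) + 1]] <<- acc + lt[L + 1, paste0(state, "M")]
        }
        if (k < L && pos < n) {  # -> M_{k+1}, emit
          t <- lt[k + 1, paste0(state, "M")]
          if (is.finite(t)) rec("M", k + 1, pos + 1,
                                acc + t + lM[k + 1, idx[pos + 1]])
        }
        if (state == "M" && k < L && pos < n) {  # -> I_k, emit
          t <- lt[k + 1, "MI"]
          if (is.finite(t)) rec("I", k, pos + 1, acc + t + lI[k + 1, idx[pos + 1]])
        }
        if (k < L) {             # -> D_{k+1}
          t <- lt[k + 1, paste0(state, "D")]
          if (is.finite(t)) rec("D", k + 1, pos, acc + t)
        }
      } else {                   # insert state I_k
        if (k < L && pos < n) {
          t <- lt[k + 1, "IM"]
          if (is.finite(t)) rec("M", k + 1, pos + 1,
                                acc + t + lM[k + 1, idx[pos + 1]])
        }
        if (pos < n) {
          t <- lt[k + 1, "II"]
          if (is.finite(t)) rec("I", k, pos + 1, acc + t + lI[k + 1, idx[pos + 1]])
        }
        if (k == L - 1 || k == L) { } # I cannot reach End directly
      }
    }
    # from Begin (node 0): M_1 / I_0 / D_1
    if (n >= 1 && is.finite(lt[1, "MM"]))
      rec("M", 1, 1, lt[1, "MM"] + lM[1, idx[1]])
    if (n >= 1 && is.finite(lt[1, "MI"]))
      rec("I", 0, 1, lt[1, "MI"] + lI[1, idx[1]])
    if (is.finite(lt[1, "MD"])) rec("D", 1, 0, lt[1, "MD"])
    # special case: Begin -> M_1 at k == L (L == 1)
  } else {
    entry <- log2(2 / (L * (L + 1)))
    rec <- function(state, k, pos, acc) {
      if (state == "M") scores[[length(scores) + 1]] <<- acc  # end fragment
      if (state %in% c("M", "D")) {
        if (k < L && pos < n) {
          t <- lt[k + 1, paste0(state, "M")]
          if (is.finite(t)) rec("M", k + 1, pos + 1,
                                acc + t + lM[k + 1, idx[pos + 1]])
        }
        if (state == "M" && k <= L - 1 && k >= 1 && pos < n) {
          t <- lt[k + 1, "MI"]
          if (is.finite(t)) rec("I", k, pos + 1, acc + t + lI[k + 1, idx[pos + 1]])
        }
        if (k < L) {
          t <- lt[k + 1, paste0(state, "D")]
          if (is.finite(t)) rec("D", k + 1, pos, acc + t)
        }
      } else {
        if (k < L && pos < n) {
          t <- lt[k + 1, "IM"]
          if (is.finite(t)) rec("M", k + 1, pos + 1,
                                acc + t + lM[k + 1, idx[pos + 1]])
        }
        if (pos < n) {
          t <- lt[k + 1, "II"]
          if (is.finite(t)) rec("I", k, pos + 1, acc + t + lI[k + 1, idx[pos + 1]])
        }
      }
    }
    for (i in seq_len(L))
      for (a in seq_len(n))
        rec("M", i, a, entry + lM[i, idx[a]])
  }
  unlist(scores)
}

oracle_viterbi <- function(hmm, seq, mode) {
  s <- enumerate_path_scores(hmm, seq, mode)
  if (length(s) == 0) -Inf else max(s)
}

oracle_forward <- function(hmm, seq, mode) {
  s <- enumerate_path_scores(hmm, seq, mode)
  if (length(s) == 0) -Inf else {
    m <- max(s)
    m + log2(sum(2^(s - m)))
  }
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n+m, n) rank assignments (requires untied data)
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  all_r <- seq_len(n + m)
  us <- apply(combs, 2, function(ix) sum(all_r[ix]) - n * (n + 1) / 2)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}
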