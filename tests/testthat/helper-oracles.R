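# Independent oracles used across the suite.

# Exhaustive enumeration of all valid secondary structures (non-crossing,
# complementary incl. G-U wobble, minimum hairpin loop) for short sequences.
# Returns candidate pair list and every structure as an index set.
enum_structures <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  cand <- list()
  if (n > min_loop + 1) {
    for (i in 1:(n - min_loop - 1)) {
      for (j in (i + min_loop + 1):n) {
        if (ok(s[i], s[j])) cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  res <- list()
  rec <- function(idx, chosen) {
    res[[length(res) + 1]] <<- chosen
    if (idx > length(cand)) return()
    for (k in idx:length(cand)) {
      p <- cand[[k]]
      okadd <- TRUE
      if (length(chosen)) {
        for (q in chosen) {
          qq <- cand[[q]]
          if (p[1] %in% qq || p[2] %in% qq) { okadd <- FALSE; break }
          if ((qq[1] < p[1] && p[1] < qq[2] && qq[2] < p[2]) ||
              (p[1] < qq[1] && qq[1] < p[2] && p[2] < qq[2])) {
            okadd <- FALSE; break
          }
        }
      }
      if (okadd) rec(k + 1, c(chosen, k))
    }
  }
  rec(1, integer(0))
  list(cand = cand, structs = res)
}

brute_max_pairs <- function(seq, min_loop = 3) {
  e <- enum_structures(seq, min_loop)
  max(vapply(e$structs, length, integer(1)))
}

brute_pair_probs <- function(seq, min_loop = 3, beta = 1) {
  e <- enum_structures(seq, min_loop)
  n <- nchar(seq)
  w <- vapply(e$structs, function(ch) exp(beta * length(ch)), numeric(1))
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (si in seq_along(e$structs)) {
    for (k in e$structs[[si]]) {
      p <- e$cand[[k]]
      P[p[1], p[2]] <- P[p[1], p[2]] + w[si]
    }
  }
  P <- P / Z
  P + t(P)
}

# expected ensemble defect by direct enumeration over the Boltzmann ensemble
brute_ensemble_defect <- function(seq, target, min_loop = 3, beta = 1) {
  e <- enum_structures(seq, min_loop)
  n <- nchar(seq)
  tgt <- db_pairs(target)
  partner_t <- rep(0L, n)
  if (nrow(tgt)) {
    partner_t[tgt[, 1]] <- tgt[, 2]
    partner_t[tgt[, 2]] <- tgt[, 1]
  }
  w <- vapply(e$structs, function(ch) exp(beta * length(ch)), numeric(1))
  Z <- sum(w)
  defect <- 0
  for (si in seq_along(e$structs)) {
    partner_s <- rep(0L, n)
    for (k in e$structs[[si]]) {
      p <- e$cand[[k]]
      partner_s[p[1]] <- p[2]
      partner_s[p[2]] <- p[1]
    }
    defect <- defect + w[si] * sum(partner_s != partner_t)
  }
  defect / Z
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# relative-error numerical gradient check for a network's parameters
nn_grad_check <- function(net, x, y, n_probe = 5, eps = 1e-5) {
  ns <- asNamespace("toeholdr")
  fw <- ns$.nn_forward(net, x, training = FALSE)
  ls <- ns$.nn_loss(fw$out, y, net$loss)
  bw <- ns$.nn_backward(fw$net, fw$caches, ls$dout)
  worst <- 0
  for (li in seq_along(net$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      p <- net$layers[[li]]$params[[pn]]
      for (k in sample(length(p), min(n_probe, length(p)))) {
        net2 <- net
        net2$layers[[li]]$params[[pn]][k] <- p[k] + eps
        l1 <- ns$.nn_loss(ns$.nn_forward(net2, x, FALSE)$out, y, net$loss)$value
        net2$layers[[li]]$params[[pn]][k] <- p[k] - eps
        l2 <- ns$.nn_loss(ns$.nn_forward(net2, x, FALSE)$out, y, net$loss)$value
        num <- (l1 - l2) / (2 * eps)
        worst <- max(worst, abs(num - g[[pn]][k]) /
                       max(1e-6, abs(num) + abs(g[[pn]][k])))
      }
    }
  }
  worst
}
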