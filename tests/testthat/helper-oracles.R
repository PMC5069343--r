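# Independent oracles used to cross-check the package implementation.
# These deliberately re-derive results with different algorithms.

# Full-canvas single-view template (every pixel inside the body).
full_template <- function(n, m = n) body_template(matrix(TRUE, n, m))

# Brute-force flood-fill connected-component labeling (stack-based),
# with the same ordering rule as label_connected (size desc, ties by
# top-left-most pixel in row-major order) so label matrices compare
# exactly. Domains (views) are respected via `domain`.
flood_fill_label <- function(binary, connectivity, domain = NULL) {
  nr <- nrow(binary); nc <- ncol(binary)
  if (is.null(domain)) domain <- matrix(1L, nr, nc)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8)
    rbind(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!binary[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbrs))) {
        q <- p + nbrs[k, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (!binary[q[1], q[2]] || lab[q[1], q[2]] != 0L) next
        if (domain[q[1], q[2]] != domain[p[1], p[2]]) next
        lab[q[1], q[2]] <- nxt
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  k <- max(lab)
  if (k == 0L) return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab, nbins = k)
  rm_rank <- (row(lab) - 1L) * nc + col(lab)
  first <- vapply(seq_len(k), function(i) min(rm_rank[lab == i]), numeric(1))
  ord <- order(-sizes, first)
  relab <- integer(k); relab[ord] <- seq_len(k)
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  list(labels = out, sizes = sizes[ord])
}

# Vectorized iterative minimum-label propagation: an algorithmically
# different component labeler, fast enough for high-repetition null
# simulations. Returns the maximum component size of a binary matrix.
propagate_max_cluster <- function(binary, connectivity) {
  if (!any(binary)) return(0L)
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(Inf, nr, nc)
  lab[binary] <- which(binary)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- if (connectivity == 8)
    list(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift(lab, o[1], o[2]))
    new[!binary] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  max(table(lab[binary]))
}

# Textbook sums-of-squares decomposition of a balanced two-way layout
# with interaction; p-values from the F distribution.
anova_ss_oracle <- function(scores) {
  a <- factor(scores$stimulus_type)
  b <- factor(scores$stimulus_location)
  y <- scores$score
  N <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  nab <- table(a, b)
  na <- table(a); nb <- table(b)
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  ss_cells <- sum(nab * (mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  ss_w <- ss_tot - ss_cells
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_w <- N - nlevels(a) * nlevels(b)
  ms_w <- ss_w / df_w
  Fs <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_w
  list(F_stimulus = Fs[1], F_location = Fs[2], F_interaction = Fs[3],
       p_stimulus = pf(Fs[1], df_a, df_w, lower.tail = FALSE),
       p_location = pf(Fs[2], df_b, df_w, lower.tail = FALSE),
       p_interaction = pf(Fs[3], df_ab, df_w, lower.tail = FALSE),
       ss = c(stim = ss_a, loc = ss_b, inter = ss_ab, within = ss_w,
              total = ss_tot))
}

# Random balanced 2x4 questionnaire-like table for one item.
random_balanced_item <- function(n_per_cell = 25, sd = 0.8) {
  g <- expand.grid(stimulus_type = c("acupuncture", "tactile"),
                   stimulus_location = c("HT7", "PC6", "ST36", "SP10"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  g$score <- rnorm(nrow(g), mean = 1, sd = sd)
  g
}

# Two-sample Kolmogorov-Smirnov distance between empirical distributions
# of non-negative integers.
ks_distance <- function(x, y) {
  grid <- 0:max(x, y)
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}
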