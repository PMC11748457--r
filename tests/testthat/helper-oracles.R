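# Independent brute-force oracles used to check the package's own
# implementations. These deliberately share no code with R/.

# AUC by exhaustive concordant-pair counting
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# TSS at a fixed threshold (predict present iff score > threshold)
tss_at <- function(scores, labels, th) {
  pred <- as.integer(scores > th)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# best achievable TSS over every distinct score used as threshold
best_tss_bruteforce <- function(scores, labels) {
  cands <- c(sort(unique(scores)), min(scores) - 1)
  max(vapply(cands, function(th) tss_at(scores, labels, th), 0))
}

# exhaustive Fisher-Jenks: minimal within-class SSD over all placements
# of k-1 breaks between sorted values
jenks_bruteforce_wssd <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  combos <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    cuts <- c(0, combos[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ssd(v[(cuts[i] + 1):cuts[i + 1]])
    if (tot < best) best <- tot
  }
  best
}

# likelihood-ratio G from the textbook decomposition
# G = 2 * [ sum O ln O - sum R ln R - sum C ln C + N ln N ]
g_bruteforce <- function(tab) {
  xlx <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  2 * (xlx(as.vector(tab)) - xlx(rowSums(tab)) - xlx(colSums(tab)) +
         xlx(sum(tab)))
}

# greedy-in-priority collinearity filter as lexicographically maximal
# pairwise-compatible subset, by explicit enumeration
pearson_filter_bruteforce <- function(cor_mat, threshold) {
  p <- nrow(cor_mat)
  best <- NULL
  for (mask in seq_len(2^p) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    if (length(sel) < 1) next
    ok <- TRUE
    if (length(sel) > 1) {
      sub <- abs(cor_mat[sel, sel])
      ok <- all(sub[upper.tri(sub)] <= threshold)
    }
    if (!ok) next
    inc <- as.integer(seq_len(p) %in% sel)
    if (is.null(best) ||
        (paste(inc, collapse = "") > paste(best, collapse = ""))) {
      best <- inc
    }
  }
  which(best == 1)
}

# tiny deterministic classified map for rubric tests
make_classified <- function(classes, cell_size_km = 1, origin = c(105, 24)) {
  structure(list(classes = classes, breaks = c(0.25, 0.5, 0.75),
                 n_classes = 4L,
                 geometry = list(origin = c(lon = origin[1], lat = origin[2]),
                                 cell_size_km = cell_size_km,
                                 n_rows = nrow(classes), n_cols = ncol(classes)),
                 provenance = "test"),
            class = "classified_map")
}

# stack of hand-built layers on the standard geometry
make_stack <- function(layers, categorical = list(), cell_size_km = 1) {
  env_stack(layers, categorical, cell_size_km = cell_size_km,
            origin = c(105, 24))
}
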