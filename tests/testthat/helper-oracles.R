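# Independent brute-force oracles used to pin down the image operations.
# These are deliberately naive re-implementations (plain double loops over
# offsets) sharing only the documented contracts with the package code.

# grayscale erosion/dilation with the ball-top SE; skip out-of-bounds
oracle_ball_op <- function(img, r, dilate = FALSE, flat = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(if (dilate) -Inf else Inf, nr, nc)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  offs$h <- if (flat) 0 else sqrt(r^2 - offs$dr^2 - offs$dc^2)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- if (dilate) img[ii, jj] + offs$h[k] else img[ii, jj] - offs$h[k]
      if (dilate) out[i, j] <- max(out[i, j], v)
      else out[i, j] <- min(out[i, j], v)
    }
  }
  out
}

oracle_rolling_ball <- function(img, r) {
  opened <- oracle_ball_op(oracle_ball_op(img, r, dilate = FALSE), r,
                           dilate = TRUE)
  pmax(img - opened, 0)
}

# exhaustive Otsu: minimise within-class weighted variance over all 255
# cut points of the 256-bin histogram; returns the foreground assignment
oracle_otsu_assign <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * 256) + 1L, 256L)
  best <- Inf; best_cut <- NA
  for (cut in 1:255) {
    g0 <- v[bin <= cut]; g1 <- v[bin > cut]
    if (length(g0) == 0 || length(g1) == 0) next
    # within-class variance about the bin-centre class means
    centers <- lo + (bin - 0.5) * (hi - lo) / 256
    c0 <- centers[bin <= cut]; c1 <- centers[bin > cut]
    wcv <- sum((c0 - mean(c0))^2) + sum((c1 - mean(c1))^2)
    if (wcv < best) { best <- wcv; best_cut <- cut }
  }
  bin > best_cut
}

# flood-fill labelling oracle (queue-based BFS, 1-based loops)
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        ii <- p[1] + nbr[k, 1]; jj <- p[2] + nbr[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# canonical signature of a labelling partition (invariant to label names)
partition_signature <- function(lab) {
  ids <- lab[lab > 0]
  pix <- which(lab > 0)
  split(pix, ids)[order(vapply(split(pix, ids), min, 0))]
}

# sliding-window local mean with symmetric padding
oracle_local_mean <- function(img, window) {
  half <- (window - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- reflect((i - half):(i + half), nr)
    jj <- reflect((j - half):(j + half), nc)
    out[i, j] <- mean(img[ii, jj])
  }
  out
}

# per-pixel ring oracle: a background pixel belongs to the candidate set of
# nucleus k when its squared distance to any footprint pixel of k is at most
# (w + 0.5)^2; contested pixels go to the nearest nucleus centroid
oracle_rings <- function(labels, w) {
  nr <- nrow(labels); nc <- ncol(labels)
  K <- max(labels)
  cents <- lapply(seq_len(K), function(k) {
    idx <- which(labels == k)
    cbind((idx - 1) %% nr, (idx - 1) %/% nr)
  })
  centroids <- lapply(cents, colMeans)
  rings <- matrix(0L, nr, nc)
  lim <- (w + 0.5)^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (labels[i, j] > 0) next
    p <- c(i - 1, j - 1)
    cand <- which(vapply(seq_len(K), function(k) {
      any((cents[[k]][, 1] - p[1])^2 + (cents[[k]][, 2] - p[2])^2 <= lim)
    }, TRUE))
    if (length(cand) == 0) next
    d <- vapply(cand, function(k)
      sum((centroids[[k]] - p)^2), 0)
    rings[i, j] <- cand[which.min(d)]
  }
  rings
}

# small helper: render one field + segment it with given params
render_and_segment <- function(spec, params = seg_params()) {
  fr <- render_field(spec)
  seg <- segment_field(fr$field$channels$nuclei, params)
  list(fr = fr, seg = seg)
}

# fit the default classifier once per test run from the bundled fixture
bundled_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      csv <- system.file("extdata", "training_features_synthetic.csv",
                         package = "spotscreen", mustWork = TRUE)
      model <<- fit_phenotype_model(read_training_csv(csv))
    }
    model
  }
})
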