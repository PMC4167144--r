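# Independent oracle implementations and small fixture builders used across
# the suite. These deliberately use different algorithms/code paths from the
# package internals they check.

# --- geometry -------------------------------------------------------------

# convex hull area by Andrew's monotone chain + shoelace, on the 4 corner
# points of every pixel
oracle_hull_area <- function(rows, cols) {
  pts <- unique(cbind(
    rep(rows, 4) + rep(c(-0.5, -0.5, 0.5, 0.5), each = length(rows)),
    rep(cols, 4) + rep(c(-0.5, 0.5, -0.5, 0.5), each = length(cols))))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(length(rows))
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(ord) {
    h <- list()
    for (i in ord) {
      p <- pts[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(seq_len(n)); upper <- build(rev(seq_len(n)))
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  m <- nrow(hull); j <- c(2:m, 1)
  abs(sum(hull[, 1] * hull[j, 2] - hull[j, 1] * hull[, 2])) / 2
}

# --- Eq.-style oversegmentation merge oracle ------------------------------

oracle_merge_features <- function(px, a_star) {
  a <- nrow(px)
  sol <- min(a / oracle_hull_area(px[, 1], px[, 2]), 1)
  c(sol, -abs(a - a_star) / a_star)
}

# exhaustive powerset choice with the package's documented tie rules
# (max score; ties -> fewer members -> lower subset index; only positive)
oracle_merge_choice <- function(f_px, g_px_list, a_star) {
  n <- length(g_px_list)
  best_score <- 0; best_subset <- integer(0); best_nj <- 1L; best_j <- -1L
  if (n > 0) for (j in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(j, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    members <- c(list(f_px), g_px_list[sel])
    u <- do.call(rbind, members)
    fu <- oracle_merge_features(u, a_star)
    fm <- sapply(members, oracle_merge_features, a_star = a_star)
    s <- sum(fu - rowMeans(fm))
    nj <- 1L + length(sel)
    better <- s > best_score + 1e-12 ||
      (abs(s - best_score) <= 1e-12 && best_j >= 0L &&
         (nj < best_nj || (nj == best_nj && j < best_j)))
    if (better && s > 1e-12) {
      best_score <- s; best_subset <- sel; best_nj <- nj; best_j <- j
    }
  }
  best_subset
}

# --- object-matching oracle ----------------------------------------------

# loop-based reimplementation of the documented matching taxonomy
oracle_match_counts <- function(pred, gold, thr = 0.5) {
  p_labs <- sort(unique(pred[pred > 0])); g_labs <- sort(unique(gold[gold > 0]))
  p_px <- lapply(p_labs, function(l) which(pred == l))
  g_px <- lapply(g_labs, function(l) which(gold == l))
  names(p_px) <- p_labs; names(g_px) <- g_labs
  inter <- function(p, g)
    length(intersect(p_px[[as.character(p)]], g_px[[as.character(g)]]))
  g_state <- setNames(rep("open", length(g_labs)), g_labs)
  p_used <- setNames(rep(FALSE, length(p_labs)), p_labs)
  Nt <- 0L; Nunder <- 0L; Nover <- 0L
  for (p in p_labs) {
    cov <- c()
    for (g in g_labs)
      if (g_state[as.character(g)] == "open" &&
          inter(p, g) / length(g_px[[as.character(g)]]) >= 0.5)
        cov <- c(cov, g)
    if (length(cov) >= 2) {
      Nunder <- Nunder + length(cov)
      g_state[as.character(cov)] <- "under"
      p_used[as.character(p)] <- TRUE
    }
  }
  for (g in g_labs) {
    if (g_state[as.character(g)] != "open") next
    ins <- c()
    for (p in p_labs)
      if (!p_used[as.character(p)] &&
          inter(p, g) / length(p_px[[as.character(p)]]) >= 0.5)
        ins <- c(ins, p)
    if (length(ins) >= 2) {
      Nover <- Nover + length(ins) - 1L
      g_state[as.character(g)] <- "over"
      p_used[as.character(ins)] <- TRUE
    }
  }
  for (g in g_labs) {
    if (g_state[as.character(g)] != "open") next
    cand <- c()
    for (p in p_labs) {
      if (p_used[as.character(p)]) next
      i <- inter(p, g)
      if (i == 0) next
      jac <- i / (length(p_px[[as.character(p)]]) +
                    length(g_px[[as.character(g)]]) - i)
      if (jac >= thr) cand <- c(cand, p)
    }
    if (length(cand) == 1) {
      Nt <- Nt + 1L
      g_state[as.character(g)] <- "matched"
      p_used[as.character(cand)] <- TRUE
    }
  }
  list(Nt = Nt, Nunder = Nunder, Nover = Nover,
       NFP = sum(!p_used), NFN = sum(g_state == "open"))
}

# --- fixture builders -----------------------------------------------------

draw_disk <- function(m, cr, cc, radius, value) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1, floor(cr - radius)); r1 <- min(nr, ceiling(cr + radius))
  c0 <- max(1, floor(cc - radius)); c1 <- min(nc, ceiling(cc + radius))
  for (r in r0:r1) for (c in c0:c1)
    if ((r - cr)^2 + (c - cc)^2 <= radius^2) m[r, c] <- value
  m
}

gaussian_blob <- function(nr, nc, cr, cc, sigma, amp = 1) {
  outer(seq_len(nr), seq_len(nc), function(r, c)
    amp * exp(-((r - cr)^2 + (c - cc)^2) / (2 * sigma^2)))
}

# a random connected blob of roughly the requested area, placed on `canvas`
# with label `lab`, avoiding occupied pixels; returns the updated canvas
place_blob <- function(canvas, cr, cc, area, lab) {
  radius <- sqrt(area / pi)
  ecc <- runif(1, 1, 2)
  a <- radius * sqrt(ecc); b <- radius / sqrt(ecc)
  th <- runif(1, 0, pi)
  nr <- nrow(canvas); nc <- ncol(canvas)
  r0 <- max(1, floor(cr - a)); r1 <- min(nr, ceiling(cr + a))
  c0 <- max(1, floor(cc - a)); c1 <- min(nc, ceiling(cc + a))
  for (r in r0:r1) for (c in c0:c1) {
    u <- (r - cr) * cos(th) + (c - cc) * sin(th)
    v <- -(r - cr) * sin(th) + (c - cc) * cos(th)
    if ((u / a)^2 + (v / b)^2 <= 1 && canvas[r, c] == 0) canvas[r, c] <- lab
  }
  canvas
}

# random gold/pred label-map pair with planted perturbations
random_match_scene <- function(seed) {
  set.seed(seed)
  gold <- matrix(0L, 64, 64)
  n <- sample(4:7, 1)
  ctr <- matrix(NA_real_, 0, 2)
  lab <- 0L
  for (i in seq_len(n)) {
    for (try in 1:50) {
      cr <- runif(1, 8, 56); cc <- runif(1, 8, 56)
      if (nrow(ctr) == 0 ||
          all(sqrt((ctr[, 1] - cr)^2 + (ctr[, 2] - cc)^2) > 13)) break
    }
    ctr <- rbind(ctr, c(cr, cc))
    lab <- lab + 1L
    gold <- draw_disk(gold, cr, cc, runif(1, 4, 6), lab)
  }
  pred <- gold
  # random perturbations: delete, split, merge-pair, jitter, spurious blob
  for (i in seq_len(lab)) {
    op <- sample(c("keep", "keep", "keep", "delete", "split", "jitter"), 1)
    if (op == "delete") pred[pred == i] <- 0L
    if (op == "split") {
      px <- which(pred == i)
      rows <- ((px - 1) %% 64) + 1
      cut <- stats::median(rows)
      pred[px[rows > cut]] <- max(pred) + 1L
    }
    if (op == "jitter") {
      px <- which(pred == i)
      pred[px] <- 0L
      rows <- ((px - 1) %% 64) + 1 + sample(-2:2, 1)
      cols <- ((px - 1) %/% 64) + 1 + sample(-2:2, 1)
      ok <- rows >= 1 & rows <= 64 & cols >= 1 & cols <= 64
      sel <- cbind(rows, cols)[ok, , drop = FALSE]
      free <- pred[sel] == 0L
      pred[sel[free, , drop = FALSE]] <- i
    }
  }
  if (runif(1) < 0.5)
    pred <- draw_disk(pred, runif(1, 8, 56), runif(1, 8, 56), 4,
                      max(pred) + 1L)
  storage.mode(gold) <- "integer"; storage.mode(pred) <- "integer"
  list(pred = ifishquant::relabel(pred), gold = gold)
}

expect_counts_equal <- function(a, b) {
  expect_identical(
    c(Nt = a$Nt, Nunder = a$Nunder, Nover = a$Nover,
      NFP = as.integer(a$NFP), NFN = as.integer(a$NFN)),
    c(Nt = as.integer(b$Nt), Nunder = as.integer(b$Nunder),
      Nover = as.integer(b$Nover), NFP = as.integer(b$NFP),
      NFN = as.integer(b$NFN)))
}
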