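# fixtures built in code, shared across test files

# binary label_image from a predicate over pixel-centre coordinates (um)
make_mask <- function(f, nr = 64, nc = 64, ps = 1) {
  xs <- matrix((seq_len(nc) - 1) * ps, nr, nc, byrow = TRUE)
  ys <- matrix((seq_len(nr) - 1) * ps, nr, nc)
  label_image(matrix(as.numeric(f(xs, ys)), nr, nc), ps)
}

disc_mask <- function(cx, cy, r, nr = 64, nc = 64, ps = 1) {
  make_mask(function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2, nr, nc, ps)
}

# independent step-by-step accumulation oracle for track statistics
oracle_track_stats <- function(track) {
  total <- 0
  for (k in 2:nrow(track)) {
    total <- total +
      sqrt((track$x_um[k] - track$x_um[k - 1])^2 +
           (track$y_um[k] - track$y_um[k - 1])^2)
  }
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  list(total_path = total, net = net,
       persistence = if (total > 0) net / total else 0)
}

# exhaustive angle-by-angle sector count oracle
oracle_sector_fraction <- function(angles, center, width) {
  inside <- 0L
  for (a in angles) {
    d <- abs(((a - center) %% 360 + 360) %% 360)
    d <- min(d, 360 - d)
    if (d <= width / 2) inside <- inside + 1L
  }
  inside / length(angles)
}

# brute-force minimal-total-distance frame-to-frame assignment oracle
# (enumerates injective mappings; feasible pairs only; <= 6 detections)
oracle_min_assignment <- function(prev, cur, max_step) {
  np <- nrow(prev); nc2 <- nrow(cur)
  d <- outer(seq_len(np), seq_len(nc2), function(i, j) {
    sqrt((prev[i, 1] - cur[j, 1])^2 + (prev[i, 2] - cur[j, 2])^2)
  })
  best <- NULL; best_cost <- Inf; best_n <- -1L
  assign_rec <- function(i, used, links, cost, n_links) {
    if (i > np) {
      # maximize matches, then minimize cost
      if (n_links > best_n || (n_links == best_n && cost < best_cost)) {
        best <<- links; best_cost <<- cost; best_n <<- n_links
      }
      return(invisible())
    }
    assign_rec(i + 1, used, links, cost, n_links)     # i unmatched
    for (j in seq_len(nc2)) {
      if (!used[j] && d[i, j] <= max_step) {
        used[j] <- TRUE; links[i] <- j
        assign_rec(i + 1, used, links, cost + d[i, j], n_links + 1L)
        used[j] <- FALSE; links[i] <- NA_integer_
      }
    }
  }
  assign_rec(1L, rep(FALSE, nc2), rep(NA_integer_, np), 0, 0L)
  best
}

# nested-loop DEG overlap oracle
oracle_deg_overlap <- function(a, b) {
  common <- character(0); concordant <- character(0)
  for (i in seq_len(nrow(a))) {
    if (!a$significant[i]) next
    for (j in seq_len(nrow(b))) {
      if (b$gene_id[j] == a$gene_id[i] && b$significant[j]) {
        common <- c(common, a$gene_id[i])
        if (sign(a$log_fc[i]) == sign(b$log_fc[j]) &&
            a$log_fc[i] != 0 && b$log_fc[j] != 0)
          concordant <- c(concordant, a$gene_id[i])
      }
    }
  }
  list(common = sort(common), concordant = sort(concordant))
}
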