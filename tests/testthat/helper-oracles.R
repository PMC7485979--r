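# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# canonical 3-contact toy complex used across tests ("TOY-A")
toy_a <- function() {
  make_toy_complex(toy_spec(5, 8, contacts = cbind(1:3, 1:3)), id = "TOY-A")
}

toy_part <- function() chain_partition("R", "T")

# exhaustive residue-contact oracle: double loop over residues, min pairwise
# atom distance computed directly
oracle_contacts <- function(s, binder, target, cutoff = 5.0) {
  a <- s$atom
  kb <- unique(residue_key(a$chain, a$resno, a$insert)[a$chain %in% binder])
  kt <- unique(residue_key(a$chain, a$resno, a$insert)[a$chain %in% target])
  keys <- residue_key(a$chain, a$resno, a$insert)
  out <- character(0)
  for (b in kb) for (t in kt) {
    xb <- as.matrix(a[keys == b, c("x", "y", "z")])
    xt <- as.matrix(a[keys == t, c("x", "y", "z")])
    dmin <- Inf
    for (i in seq_len(nrow(xb))) for (j in seq_len(nrow(xt)))
      dmin <- min(dmin, sqrt(sum((xb[i, ] - xt[j, ])^2)))
    if (dmin < cutoff) out <- c(out, paste(b, t))
  }
  sort(out)
}

# Euler-angle rotation matrix (zyz convention)
euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# rotation-grid superposition oracle: coarse Euler grid, then 1-degree local
# grid around the best cell, then simplex polish; translation is optimal by
# centroid matching for any fixed rotation
oracle_superpose_rmsd <- function(ref, mov) {
  rc <- sweep(ref, 2, colMeans(ref))
  mc <- sweep(mov, 2, colMeans(mov))
  obj <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mc %*% t(r) - rc)^2)))
  }
  best <- NULL; bestv <- Inf
  step <- 15 * pi / 180
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step / 2, by = step)) {
        v <- obj(c(a, b, c))
        if (v < bestv) { bestv <- v; best <- c(a, b, c) }
      }
  fine <- pi / 180
  for (a in best[1] + fine * (-8:8))
    for (b in best[2] + fine * (-8:8))
      for (c in best[3] + fine * (-8:8)) {
        v <- obj(c(a, b, c))
        if (v < bestv) { bestv <- v; best <- c(a, b, c) }
      }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  min(bestv, opt$value)
}

# exhaustive minimum set cover over an explicit candidate family
oracle_min_cover <- function(cover_sets, models) {
  n <- length(cover_sets)
  for (size in seq_len(n)) {
    for (ss in combn(n, size, simplify = FALSE)) {
      if (all(models %in% unlist(cover_sets[ss]))) return(size)
    }
  }
  Inf
}

# candidate family mirroring the panel-design rule: all subsets of size
# min(k, |patch|) per patch
oracle_candidates <- function(patches, k) {
  out <- list()
  for (p in patches) {
    take <- min(k, length(p$residues))
    for (ss in combn(p$residues, take, simplify = FALSE))
      out[[length(out) + 1L]] <- ss
  }
  out
}

# direct predicate evaluation of model-filter consistency
oracle_filter <- function(epitopes, calls, sym_groups = list()) {
  expand <- function(p) {
    ch <- sub(":.*", "", p)
    rest <- sub("^[^:]+:", "", p)
    for (g in sym_groups) if (ch %in% g) return(paste0(g, ":", rest))
    p
  }
  disrupted <- calls$position[calls$status == "disrupted"]
  neutral <- calls$position[calls$status == "neutral"]
  keep <- character(0)
  for (m in names(epitopes)) {
    epi <- epitopes[[m]]
    ok <- TRUE
    for (p in disrupted) if (!any(expand(p) %in% epi)) ok <- FALSE
    for (p in neutral) if (any(expand(p) %in% epi)) ok <- FALSE
    if (ok) keep <- c(keep, m)
  }
  keep
}

# Spearman rho from first principles: Pearson correlation of mid-ranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
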