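# Fixtures built in code and independent oracles used across test files.
# Oracles are deliberately naive (double loops, grid searches) and never
# share code paths with the implementation they check.

make_atoms <- function(n, name = "CA", element = "C", resname = "ALA",
                       resid = seq_len(n), chain = "A") {
  data.frame(serial = seq_len(n), name = rep_len(name, n),
             element = rep_len(element, n), resname = rep_len(resname, n),
             resid = rep_len(resid, n), chain = rep_len(chain, n),
             icode = "", heavy = rep_len(element, n) != "H",
             stringsAsFactors = FALSE)
}

random_system <- function(n, seed, spread = 10) {
  set.seed(seed)
  molecular_system(make_atoms(n), matrix(runif(n * 3, -spread, spread), n, 3))
}

# small protein + ligand complex: n_prot CA atoms at given distances from a
# 2-atom ligand placed at the origin
prot_lig_system <- function(prot_xyz, lig_xyz = rbind(c(0, 0, 0), c(0, 0, 1.5))) {
  np <- nrow(prot_xyz); nl <- nrow(lig_xyz)
  atoms <- rbind(
    make_atoms(np),
    make_atoms(nl, name = c("O1", "C1", "P1", "P2", "R1")[seq_len(nl)],
               element = c("O", "C", "P", "P", "C")[seq_len(nl)],
               resname = "LIG", resid = np + 1L, chain = "L"))
  atoms$serial <- seq_len(np + nl)
  molecular_system(atoms, rbind(prot_xyz, lig_xyz))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# --- oracles ---------------------------------------------------------------

# all-pairs inclusive <= r filter
oracle_within <- function(xyz, ref_idx, r) {
  hits <- logical(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    for (j in ref_idx) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= r) { hits[i] <- TRUE; break }
    }
  }
  which(hits)
}

# double-loop evaluation of the distance-RMSD formula
oracle_drmsd <- function(ref_xyz, mod_xyz, lig_idx, site_idx) {
  ss <- 0; n <- 0L
  for (i in lig_idx) {
    for (j in site_idx) {
      dx <- sqrt(sum((ref_xyz[i, ] - ref_xyz[j, ])^2))
      dm <- sqrt(sum((mod_xyz[i, ] - mod_xyz[j, ])^2))
      ss <- ss + (dx - dm)^2
      n <- n + 1L
    }
  }
  sqrt(ss / n)
}

# minimum RMSD over rigid transforms by Euler-grid search plus refinement;
# independent of the SVD route
oracle_min_rmsd <- function(mobile, ref) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(ref, 2, colMeans(ref))
  euler <- function(a, b, c) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(c)
  }
  obj <- function(p) {
    rot <- euler(p[1], p[2], p[3])
    sqrt(mean(rowSums((m0 %*% t(rot) - r0)^2)))
  }
  best <- c(0, 0, 0); bv <- obj(best)
  step <- pi / 9
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step, by = step)) {
        v <- obj(c(a, b, c))
        if (v < bv) { bv <- v; best <- c(a, b, c) }
      }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# independently coded greedy neighbour clustering on an RMSD matrix
oracle_daura <- function(dm, cutoff) {
  remaining <- seq_len(nrow(dm))
  clusters <- list(); centroids <- integer(0)
  while (length(remaining) > 0L) {
    best_i <- NA_integer_; best_n <- -1L
    for (i in remaining) {
      nn <- sum(dm[i, remaining] <= cutoff)
      if (nn > best_n) { best_n <- nn; best_i <- i }
    }
    grp <- remaining[dm[best_i, remaining] <= cutoff]
    clusters[[length(clusters) + 1L]] <- grp
    centroids <- c(centroids, best_i)
    remaining <- setdiff(remaining, grp)
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, centroids)
  list(members = clusters[ord], centroids = centroids[ord], sizes = sizes[ord])
}

# escape-time order statistics by explicit ranking
oracle_rank_median <- function(times, censored) {
  key <- ifelse(censored, Inf, times)
  n <- length(key)
  sorted <- sort(key)
  rank <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
  sorted[rank]
}
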