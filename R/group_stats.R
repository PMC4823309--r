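#' Stacked per-subject connectivity maps for group inference
#'
#' @param z0,z1 Numeric matrices of Fisher-z values, voxels x subjects, for
#'   sessions T0 and T1 (same voxel order).
#' @param group Factor of length \code{ncol(z0)} with two levels; the first
#'   level is the exercise group (sign convention of the interaction map).
#' @param dim Length-3 spatial dimensions; \code{prod(dim) == nrow(z0)}.
#' @param mask Optional 3D logical analysis mask.
#' @param subjects Optional subject identifiers.
#' @return An object of class \code{fc_cohort}.
#' @export
fc_cohort <- function(z0, z1, group, dim, mask = NULL, subjects = NULL) {
  z0 <- as.matrix(z0); z1 <- as.matrix(z1)
  dim <- as.integer(dim)
  if (!all(dim(z0) == dim(z1))) stop("z0 and z1 must have equal shape", call. = FALSE)
  if (nrow(z0) != prod(dim)) stop("nrow(z0) must equal prod(dim)", call. = FALSE)
  group <- as.factor(group)
  if (length(group) != ncol(z0)) stop("one group label per subject required", call. = FALSE)
  if (nlevels(droplevels(group)) != 2L) stop("exactly 2 groups required", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim)
  structure(list(z0 = z0, z1 = z1, group = droplevels(group), dim = dim,
                 mask = mask,
                 subjects = subjects %||% paste0("S", seq_len(ncol(z0)))),
            class = "fc_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subjects x voxels matrix of T1 - T0 differences
fc_diffs <- function(fc) t(fc$z1 - fc$z0)

# vectorized pooled two-sample t over columns of D (n x v), group1 - group2
two_sample_t_cols <- function(D, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(D[g1, , drop = FALSE]); m2 <- colMeans(D[!g1, , drop = FALSE])
  ss1 <- colSums(D[g1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(D[!g1, , drop = FALSE]^2) - n2 * m2^2
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  num <- m1 - m2
  den <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- num / den
  t[den == 0 & num == 0] <- 0   # no effect and no variance: flat map
  list(t = t, df = df)
}

#' Voxelwise Group x Time interaction map
#'
#' Per voxel, the per-subject difference map \code{d = z(T1) - z(T0)} is
#' compared between groups with a pooled-variance two-sample t
#' (df = n1 + n2 - 2), which is identical to the 2x2 mixed-design ANOVA
#' interaction (F = t^2). Sign convention: first group level (exercise)
#' minus second (control).
#'
#' @param fc An [fc_cohort()].
#' @return List with 3D arrays \code{t} and \code{p} (two-sided), and
#'   scalar \code{df}.
#' @export
interaction_map <- function(fc) {
  stopifnot(inherits(fc, "fc_cohort"))
  D <- fc_diffs(fc)
  g1 <- fc$group == levels(fc$group)[1]
  if (sum(g1) < 2L || sum(!g1) < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  res <- two_sample_t_cols(D, g1)
  tarr <- array(res$t, dim = fc$dim)
  list(t = tarr, p = array(2 * stats::pt(-abs(res$t), res$df), dim = fc$dim),
       df = res$df)
}

# 26/18/6-connectivity neighbor offsets (3 x k matrix)
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6, 18 or 26", call. = FALSE)
  t(g)
}

# label connected components among the given linear voxel indices;
# returns an integer label per input index
connected_components <- function(vox_idx, dim, offsets) {
  nv <- length(vox_idx)
  if (nv == 0L) return(integer(0))
  coord <- arrayInd(vox_idx, dim)
  pos <- integer(prod(dim))
  pos[vox_idx] <- seq_len(nv)
  labels <- integer(nv)
  cur <- 0L
  d1 <- dim[1]; d12 <- dim[1] * dim[2]
  for (i in seq_len(nv)) {
    if (labels[i]) next
    cur <- cur + 1L
    stack <- i
    labels[i] <- cur
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- offsets + coord[j, ]
      ok <- nb[1, ] >= 1L & nb[1, ] <= dim[1] &
        nb[2, ] >= 1L & nb[2, ] <= dim[2] &
        nb[3, ] >= 1L & nb[3, ] <= dim[3]
      if (!any(ok)) next
      lin <- nb[1, ok] + (nb[2, ok] - 1L) * d1 + (nb[3, ok] - 1L) * d12
      p <- pos[lin]
      p <- p[p > 0L]
      p <- p[labels[p] == 0L]
      if (length(p)) {
        labels[p] <- cur
        stack <- c(stack, p)
      }
    }
  }
  labels
}

#' Form suprathreshold clusters from a voxelwise t map
#'
#' Voxels exceeding the t quantile for the uncorrected threshold
#' \code{p_thresh} (default 0.001) are grouped into connected components
#' under the chosen 3D connectivity (default 26, i.e. faces, edges and
#' corners). In two-sided mode positive and negative excursions are
#' thresholded at \code{|t| > qt(1 - p_thresh, df)} and clustered
#' separately.
#'
#' @param tmap 3D t array (e.g. from [interaction_map()]).
#' @param df Degrees of freedom of the t map.
#' @param p_thresh Uncorrected voxel-level threshold (default 0.001).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param sign \code{"two-sided"} (default), \code{"pos"} or \code{"neg"}.
#' @param mask Optional 3D logical analysis mask.
#' @return A \code{cluster_table} data frame: \code{cluster_id},
#'   \code{size_vox}, \code{peak_stat}, \code{peak_i/j/k}, \code{sign};
#'   attribute \code{voxels} holds the per-cluster linear voxel indices.
#' @export
form_clusters <- function(tmap, df, p_thresh = 0.001, connectivity = 26L,
                          sign = c("two-sided", "pos", "neg"), mask = NULL) {
  sign <- match.arg(sign)
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  dim <- dim(tmap)
  tcrit <- stats::qt(1 - p_thresh, df)
  tv <- as.numeric(tmap)
  keep <- if (is.null(mask)) rep(TRUE, length(tv)) else as.logical(mask)
  offs <- neighbor_offsets(connectivity)
  out <- list()
  vox_list <- list()
  add_sign <- function(sgn) {
    supra <- which(keep & (if (sgn > 0) tv > tcrit else tv < -tcrit))
    if (!length(supra)) return()
    lab <- connected_components(supra, dim, offs)
    for (l in seq_len(max(lab))) {
      vox <- supra[lab == l]
      pk <- vox[which.max(abs(tv[vox]))]
      pkc <- arrayInd(pk, dim)
      out[[length(out) + 1L]] <<- data.frame(
        size_vox = length(vox), peak_stat = tv[pk],
        peak_i = pkc[1], peak_j = pkc[2], peak_k = pkc[3],
        sign = if (sgn > 0) "pos" else "neg")
      vox_list[[length(vox_list) + 1L]] <<- vox
    }
  }
  if (sign %in% c("two-sided", "pos")) add_sign(1)
  if (sign %in% c("two-sided", "neg")) add_sign(-1)
  if (!length(out)) {
    tab <- data.frame(cluster_id = integer(0), size_vox = integer(0),
                      peak_stat = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      sign = character(0))
    attr(tab, "voxels") <- list()
    class(tab) <- c("cluster_table", "data.frame")
    return(tab)
  }
  tab <- do.call(rbind, out)
  ord <- order(tab$size_vox, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "voxels") <- vox_list[ord]
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# max cluster size of one thresholded map (helper for the permutation null)
max_cluster_size <- function(tv, dim, tcrit, offs, keep) {
  mx <- 0L
  for (sgn in c(1, -1)) {
    supra <- which(keep & (if (sgn > 0) tv > tcrit else tv < -tcrit))
    if (!length(supra)) next
    lab <- connected_components(supra, dim, offs)
    mx <- max(mx, max(tabulate(lab)))
  }
  mx
}

#' Permutation-based cluster-level family-wise error control
#'
#' Builds the null distribution of the maximum cluster size by randomly
#' reassigning group labels to the subjects' difference maps (subject-level
#' exchangeability under the null of no Group x Time interaction),
#' recomputing the voxelwise t map and its suprathreshold clusters for each
#' relabeling. Cluster-level
#' \code{p_fwe = (1 + #\{perm max size >= observed size\}) / (n_perm + 1)},
#' the convention that counts the observed labeling and avoids zero
#' p-values. When fewer distinct labelings than \code{n_perm} exist they are
#' enumerated exactly instead and \code{p_fwe} is the exact proportion.
#'
#' @param fc An [fc_cohort()].
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param p_thresh Cluster-forming uncorrected voxel threshold (default 0.001).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param seed Integer RNG seed for the permutation draw.
#' @return A \code{cluster_table} (see [form_clusters()]) with an added
#'   \code{p_fwe} column; attributes \code{null_max_size} (the permutation
#'   distribution), \code{df}, \code{exact} and \code{tmap}.
#' @export
permutation_cluster_fwe <- function(fc, n_perm = 1000L, p_thresh = 0.001,
                                    connectivity = 26L, seed = 1L) {
  stopifnot(inherits(fc, "fc_cohort"))
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse FWE p-value", call. = FALSE)
  D <- fc_diffs(fc)
  n <- nrow(D)
  g1 <- fc$group == levels(fc$group)[1]
  n1 <- sum(g1)
  if (n1 < 2L || n - n1 < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  obs <- two_sample_t_cols(D, g1)
  df <- obs$df
  dim <- fc$dim
  offs <- neighbor_offsets(connectivity)
  keep <- as.logical(fc$mask)
  tab <- form_clusters(array(obs$t, dim), df, p_thresh, connectivity,
                       sign = "two-sided", mask = fc$mask)
  tcrit <- stats::qt(1 - p_thresh, df)
  n_total <- choose(n, n1)
  exact <- n_total <= n_perm
  if (exact) {
    sel <- utils::combn(n, n1)
    B <- ncol(sel)
  } else {
    set.seed(as.integer(seed))
    B <- n_perm
    sel <- replicate(B, sample.int(n, n1))
  }
  # batched vectorized t maps for all relabelings
  P <- matrix(0, B, n)
  P[cbind(rep(seq_len(B), each = n1), as.integer(sel))] <- 1
  n2 <- n - n1
  S <- colSums(D); SS <- colSums(D^2)
  S1 <- P %*% D; SS1 <- P %*% (D^2)
  S2 <- matrix(S, B, ncol(D), byrow = TRUE) - S1
  SS2 <- matrix(SS, B, ncol(D), byrow = TRUE) - SS1
  ssw <- (SS1 - S1^2 / n1) + (SS2 - S2^2 / n2)
  tmat <- (S1 / n1 - S2 / n2) / sqrt(ssw / df * (1 / n1 + 1 / n2))
  null_max <- integer(B)
  for (b in seq_len(B)) {
    tv <- tmat[b, ]
    if (max(abs(tv[keep])) > tcrit) {
      null_max[b] <- max_cluster_size(tv, dim, tcrit, offs, keep)
    }
  }
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$size_vox, function(sz) {
      if (exact) mean(null_max >= sz)
      else (1 + sum(null_max >= sz)) / (n_perm + 1)
    }, numeric(1))
  } else {
    tab$p_fwe <- numeric(0)
  }
  attr(tab, "null_max_size") <- null_max
  attr(tab, "df") <- df
  attr(tab, "exact") <- exact
  attr(tab, "tmap") <- array(obs$t, dim)
  tab
}

#' Post-hoc t-tests on cohort scalars or cluster means
#'
#' \code{kind = "paired"} compares the two vectors within subjects;
#' \code{kind = "two-sample"} compares independent groups, by default with
#' pooled variance (\code{var_equal = FALSE} gives Welch). Zero-variance
#' input yields an infinite or NaN statistic with \code{degenerate = TRUE}
#' rather than an error.
#'
#' @param x,y Numeric vectors (paired: equal length).
#' @param kind \code{"paired"} or \code{"two-sample"}.
#' @param var_equal Pooled variance for the two-sample case (default TRUE).
#' @return List with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{degenerate}.
#' @export
posthoc_t <- function(x, y, kind = c("paired", "two-sample"),
                      var_equal = TRUE) {
  kind <- match.arg(kind)
  if (kind == "paired") {
    if (length(x) != length(y)) stop("paired vectors must have equal length", call. = FALSE)
    if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
    d <- x - y
    n <- length(d)
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    df <- n - 1L
    list(t = t, df = df,
         p = if (is.finite(t)) 2 * stats::pt(-abs(t), df) else if (is.nan(t)) NaN else 0,
         degenerate = !is.finite(t))
  } else {
    if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group", call. = FALSE)
    if (var_equal) {
      pooled_t(x, y)
    } else {
      n1 <- length(x); n2 <- length(y)
      v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
      t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
      list(t = t, df = df,
           p = if (is.finite(t)) 2 * stats::pt(-abs(t), df) else if (is.nan(t)) NaN else 0,
           degenerate = !is.finite(t))
    }
  }
}

#' MANOVA on the Group x Time interaction of autonomic scalars
#'
#' One-way MANOVA of the per-subject T1 - T0 difference vectors between
#' groups (equivalent to the 2x2 mixed-design interaction): Wilks' Lambda =
#' det(E) / det(E + H) with Rao's F approximation, as in the usual SPSS
#' output. With a single variable the result reduces exactly to the
#' univariate two-sample ANOVA F.
#'
#' @param table Long cohort data frame with columns \code{subject_id},
#'   \code{group}, \code{session} and the variables.
#' @param variables Character vector of scalar columns (default
#'   \code{c("hr_bpm", "rmssd_ms", "vt_power_w")}).
#' @return List with \code{wilks}, \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
manova_group_time <- function(table,
                              variables = c("hr_bpm", "rmssd_ms", "vt_power_w")) {
  missing_cols <- setdiff(c("subject_id", "group", "session", variables),
                          names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  diffs <- sapply(variables, function(v) {
    w <- reshape_sessions(data.frame(subject = table$subject_id,
                                     group = table$group,
                                     session = table$session,
                                     value = table[[v]]), "value")
    w$T1 - w$T0
  })
  diffs <- as.matrix(diffs)
  w0 <- reshape_sessions(data.frame(subject = table$subject_id,
                                    group = table$group,
                                    session = table$session,
                                    value = table[[variables[1]]]), "value")
  grp <- factor(w0$group)
  n <- nrow(diffs); p <- ncol(diffs)
  if (p >= n - 1L) stop("more variables than error degrees of freedom", call. = FALSE)
  if (p == 1L) {
    a <- stats::anova(stats::lm(diffs[, 1] ~ grp))
    return(list(wilks = a$`Sum Sq`[2] / sum(a$`Sum Sq`), F = a$`F value`[1],
                df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1]))
  }
  fit <- stats::manova(diffs ~ grp)
  s <- summary(fit, test = "Wilks")$stats
  list(wilks = s["grp", "Wilks"], F = s["grp", "approx F"],
       df1 = s["grp", "num Df"], df2 = s["grp", "den Df"],
       p = s["grp", "Pr(>F)"])
}

#' Correlation of connectivity change with an autonomic change
#'
#' For the exercise-group subjects, the mean Fisher-z over a cluster's
#' voxels at T1 minus the same at T0 is correlated (Pearson, two-sided
#' t-based p at df = n - 2) with the corresponding change in a scalar
#' autonomic measure - the headline association between connectivity change
#' and RMSSD change.
#'
#' @param fc An [fc_cohort()].
#' @param cluster_voxels Integer linear voxel indices of the cluster (e.g.
#'   one element of \code{attr(cluster_table, "voxels")}).
#' @param delta_scalar Named or ordered numeric vector of per-subject scalar
#'   changes, one per exercise-group subject (in the cohort's subject
#'   order).
#' @param group_level Group whose subjects enter the correlation (default
#'   the first level, exercise).
#' @return List with \code{r}, \code{p}, \code{n}, and the per-subject
#'   \code{delta_fc}.
#' @export
delta_correlation <- function(fc, cluster_voxels, delta_scalar,
                              group_level = levels(fc$group)[1]) {
  stopifnot(inherits(fc, "fc_cohort"))
  if (!length(cluster_voxels)) stop("empty cluster", call. = FALSE)
  sel <- fc$group == group_level
  if (sum(sel) < 3L) stop("need at least 3 subjects for a correlation", call. = FALSE)
  dz <- colMeans(fc$z1[cluster_voxels, sel, drop = FALSE]) -
    colMeans(fc$z0[cluster_voxels, sel, drop = FALSE])
  if (length(delta_scalar) != sum(sel)) {
    stop("delta_scalar must have one value per subject of the chosen group",
         call. = FALSE)
  }
  ct <- stats::cor.test(dz, as.numeric(delta_scalar), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(sel), delta_fc = dz)
}
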