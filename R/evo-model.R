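## Structure metaprofiles, bootstrap comparison, substitution-rate
## profiles and the logistic gain/loss model.

## dot-bracket list -> pairing matrix aligned on the site (NA where the
## window is padded / truncated)
pairing_matrix <- function(dbs, window) {
  p <- 2L * window + 1L
  out <- matrix(NA_real_, nrow = length(dbs), ncol = p)
  for (i in seq_along(dbs)) {
    db <- dbs[[i]]
    v <- pairingVector(db)
    L <- length(v)
    center <- (L + 1L) %/% 2L
    lo <- center - window; hi <- center + window
    src <- max(1L, lo):min(L, hi)
    out[i, src - lo + 1L] <- v[src]
  }
  colnames(out) <- paste0("offset_", -window:window)
  out
}

## contexts may carry N-padding; padded positions do not contribute
mask_padding <- function(M, seqs, window) {
  if (is.null(seqs)) return(M)
  for (i in seq_along(seqs)) {
    chars <- seq_chars(seqs[[i]])
    center <- (length(chars) + 1L) %/% 2L
    lo <- center - window
    src <- max(1L, lo):min(length(chars), center + window)
    pad <- chars[src] == "N"
    M[i, (src - lo + 1L)[pad]] <- NA_real_
  }
  M
}

#' Base-pairing metaprofile around sites
#'
#' Mean paired-status per offset across structure contexts, aligned on
#' the site (window center). Positions short of flank (truncated or
#' padded) are excluded from their column's denominator.
#'
#' @param dbs Character vector of dot-bracket strings, site at the
#'   central position.
#' @param window Half-window size (offsets `-window..window`).
#' @param seqs Optional matching sequences; positions marked `N` are
#'   treated as absent.
#' @return `data.frame`: offset, frequency, n.
#' @export
pairingMetaprofile <- function(dbs, window = 50L, seqs = NULL) {
  if (length(dbs) == 0L) stop("need at least one context", call. = FALSE)
  M <- mask_padding(pairing_matrix(dbs, window), seqs, window)
  data.frame(offset = -window:window,
             frequency = colMeans(M, na.rm = TRUE),
             n = colSums(!is.na(M)))
}

#' Bootstrap comparison of base-pairing frequencies
#'
#' Repeatedly down-samples `n_sample` structures (without replacement)
#' from each group, records per-position pairing frequencies across
#' `n_boot` replicates, and compares the two replicate samples per
#' position with a Student's t-test. The one-sided direction is taken
#' from the sign of the full-data frequency difference; both one- and
#' two-sided p-values are reported.
#'
#' @param dbsA,dbsB Dot-bracket vectors per group (site centered).
#' @param window Half-window.
#' @param n_sample Structures drawn per replicate (default 100).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (deterministic output for fixed seed).
#' @param seqsA,seqsB Optional sequences for padding masks.
#' @return `data.frame`: offset, freqA, freqB, boot_meanA, boot_meanB,
#'   direction, p_one_sided, p_two_sided; bootstrap frequency arrays are
#'   attached as attributes `bootA`/`bootB` (n_boot x positions).
#' @export
bootstrapPairingTest <- function(dbsA, dbsB, window = 50L, n_sample = 100L,
                                 n_boot = 1000L, seed = 1L,
                                 seqsA = NULL, seqsB = NULL) {
  if (length(dbsA) < n_sample || length(dbsB) < n_sample) {
    stop(sprintf(
      "each group needs >= n_sample (%d) contexts; reduce n_sample",
      n_sample), call. = FALSE)
  }
  MA <- mask_padding(pairing_matrix(dbsA, window), seqsA, window)
  MB <- mask_padding(pairing_matrix(dbsB, window), seqsB, window)
  with_seed(seed, {
    bootA <- matrix(NA_real_, n_boot, ncol(MA))
    bootB <- matrix(NA_real_, n_boot, ncol(MB))
    for (r in seq_len(n_boot)) {
      bootA[r, ] <- colMeans(MA[sample.int(nrow(MA), n_sample), ,
                                drop = FALSE], na.rm = TRUE)
      bootB[r, ] <- colMeans(MB[sample.int(nrow(MB), n_sample), ,
                                drop = FALSE], na.rm = TRUE)
    }
    fullA <- colMeans(MA, na.rm = TRUE)
    fullB <- colMeans(MB, na.rm = TRUE)
    mA <- colMeans(bootA); mB <- colMeans(bootB)
    vA <- apply(bootA, 2L, stats::var); vB <- apply(bootB, 2L, stats::var)
    se <- sqrt(vA / n_boot + vB / n_boot)
    tstat <- (mA - mB) / se
    df <- (vA / n_boot + vB / n_boot)^2 /
      ((vA / n_boot)^2 / (n_boot - 1) + (vB / n_boot)^2 / (n_boot - 1))
    direction <- ifelse(fullA - fullB >= 0, 1L, -1L)
    p_one <- pt(direction * tstat, df, lower.tail = FALSE)
    p_two <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    zero <- !is.finite(tstat)  # identical constant columns
    p_one[zero] <- 1; p_two[zero] <- 1
    out <- data.frame(offset = -window:window, freqA = fullA, freqB = fullB,
                      boot_meanA = mA, boot_meanB = mB,
                      direction = direction,
                      p_one_sided = p_one, p_two_sided = pmin(p_two, 1))
    attr(out, "bootA") <- bootA
    attr(out, "bootB") <- bootB
    out
  })
}

#' Per-position substitution rate around orthologous sites
#'
#' Fraction of site pairs whose bases differ at each offset, per
#' conservation group. Expects aligned flank windows (site centered,
#' `N`-padded ends ignored).
#'
#' @param seqsA,seqsB Aligned window sequences per site (same order).
#' @param groups Per-site group label (e.g. conserved / A_specific).
#' @param window Half-window of offsets to report.
#' @return `data.frame`: group, offset, n_pairs, rate.
#' @export
substitutionRateProfile <- function(seqsA, seqsB, groups, window = 10L) {
  stopifnot(length(seqsA) == length(seqsB),
            length(groups) == length(seqsA))
  offs <- -window:window
  rows <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    diff_count <- integer(length(offs)); n_count <- integer(length(offs))
    for (i in sel) {
      a <- seq_chars(seqsA[i]); b <- seq_chars(seqsB[i])
      center <- (length(a) + 1L) %/% 2L
      for (j in seq_along(offs)) {
        k <- center + offs[j]
        if (k >= 1L && k <= length(a) && a[k] != "N" && b[k] != "N") {
          n_count[j] <- n_count[j] + 1L
          if (a[k] != b[k]) diff_count[j] <- diff_count[j] + 1L
        }
      }
    }
    rows[[g]] <- data.frame(group = g, offset = offs, n_pairs = n_count,
                            rate = ifelse(n_count > 0L,
                                          diff_count / n_count, NA_real_))
  }
  do.call(rbind, rows)
}

## feature offsets for the gain/loss design
BASE_OFFSETS <- c(-2L, -1L, 1L, 2L, 3L, 4L, 5L)

offset_label <- function(off) {
  ifelse(off < 0L, paste0("m", -off), ifelse(off > 0L, paste0("p", off), "0"))
}

#' Sequence/structure feature matrix for the gain/loss model
#'
#' Encodes each site context into the binary features of the logistic
#' gain/loss model. Type I: base identity at offsets -2..+5 (site
#' omitted; one-hot with the reference base dropped) plus paired status
#' at every offset of the +/-50 window (101 features, 122 total).
#' Type II: paired status over -20..+20 only (41 features). `N`-padded
#' positions contribute zeros.
#'
#' @param seqs Window sequences (site centered, odd length).
#' @param dbs Matching dot-bracket strings.
#' @param mode `"TypeI"` or `"TypeII"`.
#' @param reference Reference category per base position: a fixed base
#'   (default `"A"`, so generated and refitted designs align) or
#'   `"most_frequent"` to drop the modal base per position.
#' @return Numeric matrix with named columns (`base_<off>_<B>`,
#'   `pair_<off>`).
#' @export
featureMatrix <- function(seqs, dbs, mode = c("TypeI", "TypeII"),
                          reference = "A") {
  mode <- match.arg(mode)
  n <- length(seqs)
  stopifnot(length(dbs) == n)
  pair_window <- if (mode == "TypeI") 50L else 20L
  P <- pairing_matrix(dbs, pair_window)
  P <- mask_padding(P, seqs, pair_window)
  P[is.na(P)] <- 0
  colnames(P) <- paste0("pair_", offset_label(-pair_window:pair_window))
  if (mode == "TypeII") return(P)
  ## base one-hot block
  base_cols <- list()
  chars <- lapply(seqs, seq_chars)
  centers <- vapply(chars, function(x) (length(x) + 1L) %/% 2L, 0L)
  for (off in BASE_OFFSETS) {
    b <- vapply(seq_len(n), function(i) {
      k <- centers[i] + off
      if (k >= 1L && k <= length(chars[[i]])) chars[[i]][k] else "N"
    }, character(1))
    if (identical(reference, "most_frequent")) {
      tab <- table(factor(b[b %in% RNA_BASES], levels = RNA_BASES))
      ref <- names(tab)[which.max(tab)]
    } else {
      ref <- reference
    }
    keep <- setdiff(RNA_BASES, ref)
    for (bb in keep) {
      base_cols[[paste0("base_", offset_label(off), "_", bb)]] <-
        as.numeric(b == bb)
    }
  }
  X <- cbind(do.call(cbind, base_cols), P)
  colnames(X) <- c(names(base_cols), colnames(P))
  X
}

#' Build the labeled gain/loss design from a species pair
#'
#' For each site methylated in exactly one species (and C at the DNA
#' level in both), the methylated species' context contributes a
#' positive example (label 1) and the unmethylated species' context a
#' negative one (label 0); feature interactions are not considered.
#'
#' @param pair Result of [makeSpeciesPair()] (or a list with
#'   `site_truth` and `contexts` of the same shape).
#' @param mode `"TypeI"` or `"TypeII"` (sites of the other class are
#'   dropped).
#' @param reference Dummy-coding reference, see [featureMatrix()].
#' @return List with `X` (feature matrix), `y` (labels) and `site_id`.
#' @export
buildDesign <- function(pair, mode = c("TypeI", "TypeII"),
                        reference = "A") {
  mode <- match.arg(mode)
  st <- pair$site_truth
  ctx <- pair$contexts
  ## planted sites are methylated in A; discordant = lost in B
  sel <- st$planted_type == mode & st$baseB == "C" & !st$methylated_b
  if (!any(sel)) stop("no discordant sites for mode ", mode, call. = FALSE)
  ids <- st$site_id[sel]
  ca <- ctx[ctx$species == "A", ]
  cb <- ctx[ctx$species == "B", ]
  ca <- ca[match(ids, ca$site_id), ]
  cb <- cb[match(ids, cb$site_id), ]
  X <- rbind(featureMatrix(ca$seq, ca$db, mode, reference),
             featureMatrix(cb$seq, cb$db, mode, reference))
  y <- c(rep(1L, length(ids)), rep(0L, length(ids)))
  list(X = X, y = y, site_id = c(ids, ids))
}

#' Fit the logistic gain/loss GLM
#'
#' Ridge-stabilized Bernoulli log-likelihood with logit link, maximized
#' by iteratively reweighted least squares (Newton steps on the
#' penalized likelihood). Convergence requires the maximum coefficient
#' change to drop below `tol` within `max_iter` iterations; complete
#' separation without ridge is reported as non-convergence, never
#' silently returned as converged.
#'
#' @param X Feature matrix (no intercept column; one is added).
#' @param y 0/1 labels.
#' @param ridge Ridge penalty on non-intercept coefficients (default
#'   `1e-6`; set 0 for an exact GLM).
#' @param max_iter,tol IRLS controls.
#' @return A [GLMFit-class].
#' @export
fitLogistic <- function(X, y, ridge = 1e-6, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - pen * beta
    H <- crossprod(X1 * w, X1) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, p), grad)
    })
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X1 %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X1 * w, X1) + diag(pen, p)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) {
    rep(NA_real_, p)
  })
  if (!converged) {
    warning("IRLS did not converge (possible complete separation); ",
            "coefficients are reported with converged = FALSE")
  }
  new("GLMFit",
      coefficients = setNames(beta, colnames(X1)),
      se = setNames(se, colnames(X1)),
      converged = converged,
      n_pos = as.integer(sum(y == 1)), n_neg = as.integer(sum(y == 0)),
      iterations = it)
}
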