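## Repeat-family cis-modifier analysis: consensus alignment, k-mer presence,
## single and conditional logistic association with forward selection under
## Bonferroni control, additive DNA-based scoring, and the co-binding GLM.

#' Align repeat copies to their family consensus
#'
#' Global (Needleman-Wunsch) alignment with affine gaps (match +1,
#' mismatch -1; a gap of length L costs 5 + L) of each copy against the
#' consensus, recording for every copy base its consensus coordinate (or
#' `NA` at insertions). Gap-placement ties follow the deterministic choice
#' of the underlying aligner. Copies shorter than half the consensus
#' length are flagged and excluded from positional reporting.
#'
#' @param seqs Character vector of copy sequences (consensus orientation).
#' @param consensus Consensus sequence (length >= 50).
#' @return A list of class `ConsensusAlignment`: `map` (list of integer
#'   vectors, per-base 0-based consensus coordinates), `score` (alignment
#'   scores) and `flagged` (logical, too-short copies).
#' @export
align_to_consensus <- function(seqs, consensus) {
  if (nchar(consensus) < 50) stop("consensus shorter than 50 bp")
  flagged <- nchar(seqs) < 0.5 * nchar(consensus)
  map <- vector("list", length(seqs))
  score <- rep(NA_real_, length(seqs))
  todo <- which(!flagged)
  if (length(todo) > 0) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[todo]),
      Biostrings::DNAString(consensus),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1)
    score[todo] <- Biostrings::score(pa)
    apat <- as.character(Biostrings::alignedPattern(pa))
    asub <- as.character(Biostrings::alignedSubject(pa))
    gap <- utf8ToInt("-")
    for (j in seq_along(todo)) {
      p <- utf8ToInt(apat[j]) != gap
      s <- utf8ToInt(asub[j]) != gap
      cons_pos <- cumsum(s) - 1             # 0-based consensus coordinate
      cons_pos[!s] <- NA                    # insertion relative to consensus
      map[[todo[j]]] <- cons_pos[p]
    }
  }
  structure(list(map = map, score = score, flagged = flagged),
            class = "ConsensusAlignment")
}

#' Binary k-mer presence matrix over repeat copies
#'
#' Presence is 1 iff the k-mer occurs at least once in the copy's sequence
#' (forward strand of the consensus-aligned orientation). Columns for
#' k-mers absent from every copy are dropped. Each retained k-mer is
#' annotated with the median consensus start coordinate among its
#' occurrences when an alignment is supplied.
#'
#' @param seqs Character vector of copy sequences.
#' @param k K-mer length (5 to 12; default 7).
#' @param alignment Optional [align_to_consensus()] result for positional
#'   annotation.
#' @return A list of class `KmerMatrix`: `X` (copies x k-mers 0/1 integer
#'   matrix with k-mer column names) and `positions` (named vector of
#'   median consensus starts, `NA` without an alignment).
#' @export
kmer_presence_matrix <- function(seqs, k = 7, alignment = NULL) {
  if (k < 5 || k > 12) stop("k must be in [5, 12]")
  n <- length(seqs)
  occ <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  kmers <- sort(unique(unlist(occ)))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  X <- matrix(0L, nrow = n, ncol = length(kmers),
              dimnames = list(NULL, kmers))
  for (i in seq_len(n)) {
    hit <- occ[[i]][occ[[i]] %in% kmers]
    X[i, hit] <- 1L
  }
  positions <- setNames(rep(NA_real_, length(kmers)), kmers)
  if (!is.null(alignment)) {
    acc_w <- vector("list", n)
    acc_p <- vector("list", n)
    for (i in seq_len(n)) {
      if (alignment$flagged[i] || is.null(alignment$map[[i]])) next
      s <- seqs[i]
      L <- nchar(s)
      if (L < k) next
      starts <- 1:(L - k + 1)
      words <- substring(s, starts, starts + k - 1)
      keep <- words %in% kmers
      cp <- alignment$map[[i]][starts[keep]]
      ok <- !is.na(cp)
      acc_w[[i]] <- words[keep][ok]
      acc_p[[i]] <- cp[ok]
    }
    all_w <- unlist(acc_w, use.names = FALSE)
    all_p <- unlist(acc_p, use.names = FALSE)
    if (length(all_w)) {
      med <- tapply(all_p, all_w, median)
      positions[names(med)] <- med
    }
  }
  structure(list(X = X, positions = positions, k = k),
            class = "KmerMatrix")
}

## logistic fit via glm.fit with separation detection; returns coef, vcov,
## deviance, separated flag
logit_fit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(mu > 1 - 1e-10 & y == 1) && any(mu < 1e-10 & y == 0) &&
    max(abs(fit$coefficients)) > 10
  list(coef = fit$coefficients, deviance = fit$deviance,
       X = X, mu = mu, separated = separated)
}

logit_vcov <- function(fit) {
  w <- fit$mu * (1 - fit$mu)
  XtWX <- crossprod(fit$X * w, fit$X)
  solve(XtWX)
}

## Firth-penalized logistic regression (Jeffreys prior), used as a
## fallback under complete separation.
firth_logit <- function(X, y, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    inv <- solve(XtWX)
    ## hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2
    h <- rowSums((X %*% inv) * X) * w
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  list(coef = beta, vcov = solve(crossprod(X * w, X)))
}

#' Single logistic association of a k-mer with a binary outcome
#'
#' Fits `outcome ~ intercept + presence (+ covariates)` by maximum
#' likelihood; the presence coefficient is the log-odds ratio, the p-value
#' is the likelihood-ratio test against the model without presence. With
#' no covariates this reproduces the closed-form 2x2 log-OR and Woolf SE.
#' Complete separation is flagged and the estimate replaced by a
#' Firth-penalized fit.
#'
#' @param presence Binary (0/1) presence vector.
#' @param outcome Binary outcome vector (must contain both classes).
#' @param covariates Optional numeric matrix / data.frame of covariates.
#' @param kmer Optional k-mer label carried into the record.
#' @param position Optional consensus start coordinate.
#' @return A one-row data.frame of class `AssociationRecord`: kmer,
#'   position, beta (natural-log OR), se, p, or, separated.
#' @export
single_association <- function(presence, outcome, covariates = NULL,
                               kmer = NA_character_,
                               position = NA_real_) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X1 <- cbind(`(Intercept)` = rep(1, length(y)),
              presence = as.numeric(presence), C)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  f1 <- logit_fit(X1, y)
  f0 <- logit_fit(X0, y)
  lrt <- max(0, f0$deviance - f1$deviance)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (f1$separated) {
    ff <- firth_logit(X1, y)
    beta <- ff$coef[2]
    se <- sqrt(ff$vcov[2, 2])
  } else {
    beta <- f1$coef[2]
    se <- sqrt(logit_vcov(f1)[2, 2])
  }
  out <- data.frame(kmer = kmer, position = position, beta = beta,
                    se = se, p = p, or = exp(beta),
                    separated = f1$separated,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("AssociationRecord", "data.frame")
  out
}

## vectorized Rao score statistics for adding each column of X to a fitted
## reduced logistic model with design Z: U^2 / V with U = x'(y - mu) and
## V = x'Wx - x'WZ (Z'WZ)^-1 Z'Wx. Used only to rank candidates; the
## reported p-values come from exact LRT refits of the leaders.
score_screen <- function(X, y, Z, mu) {
  w <- mu * (1 - mu)
  U <- drop(crossprod(X, y - mu))
  WX <- X * w
  T1 <- colSums(X * WX)
  B <- crossprod(Z, WX)                       # p x m
  ZWZ <- crossprod(Z * w, Z)
  V <- T1 - colSums(B * solve(ZWZ, B))
  stat <- ifelse(V > 1e-12, U^2 / V, 0)
  stat
}

## vectorized 2x2-table LRT screen: deviance difference for each binary
## column against a binary outcome, no covariates
lrt_screen_2x2 <- function(X, y) {
  n <- length(y)
  n1 <- colSums(X)                      # present
  n0 <- n - n1
  a <- drop(crossprod(X, y))            # present & hot
  b <- n1 - a
  csum <- sum(y)
  c_ <- csum - a                        # absent & hot
  d <- n0 - c_
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  ## 2 * [ ll_full - ll_null ] for Bernoulli likelihoods
  ll_full <- xlogx(a) + xlogx(b) + xlogx(c_) + xlogx(d) -
    xlogx(n1) - xlogx(n0)
  ll_null <- xlogx(csum) + xlogx(n - csum) - xlogx(n)
  pmax(0, 2 * (ll_full - ll_null))
}

#' Greedy conditional forward selection of associated k-mers
#'
#' At each round, every remaining k-mer column is tested conditional on all
#' previously selected k-mers plus the fixed covariates; the minimum-p
#' k-mer is selected if its likelihood-ratio p-value is below the
#' Bonferroni threshold `alpha_family / ncol(X)` (the denominator counts
#' the columns actually tested, i.e. after dropping all-absent columns).
#' Selection stops otherwise. With many candidate columns, each round
#' ranks candidates by the Rao score test against the current model and
#' computes exact likelihood-ratio refits for the leaders only; reported
#' p-values are always from the LRT. Afterwards, unselected k-mers whose presence
#' correlates above `collapse_r` with a selected k-mer -- and whose
#' consensus positions overlap, when positions are available -- are
#' recorded as that selection's shadows.
#'
#' @param km A [kmer_presence_matrix()] result, or a plain 0/1 matrix with
#'   k-mer column names.
#' @param outcome Binary outcome vector.
#' @param covariates Optional covariate matrix (e.g. a PRDM9 motif score
#'   when testing conditional on binding).
#' @param alpha_family Family-wise error target (default 0.05).
#' @param collapse_r Shadow-collapse presence-correlation threshold
#'   (default 0.9).
#' @param max_terms Safety cap on selected terms (default 20).
#' @return A data.frame of class `AssociationRecord` (0 rows if nothing
#'   passes), one row per selected k-mer in selection order, with columns
#'   beta/se/p re-fit in the final joint model, `conditioning` (comma-
#'   separated k-mers selected before it) and `shadows`.
#' @export
forward_selection <- function(km, outcome, covariates = NULL,
                              alpha_family = 0.05, collapse_r = 0.9,
                              max_terms = 20) {
  X <- if (inherits(km, "KmerMatrix")) km$X else km
  positions <- if (inherits(km, "KmerMatrix")) km$positions else
    setNames(rep(NA_real_, ncol(X)), colnames(X))
  k <- if (inherits(km, "KmerMatrix")) km$k else
    nchar(colnames(X)[1])
  y <- as.numeric(outcome)
  present <- colSums(X) > 0
  X <- X[, present, drop = FALSE]
  m <- ncol(X)
  if (m == 0) return(empty_assoc())
  thresh <- alpha_family / m
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  selected <- character(0)
  records <- list()
  remaining <- colnames(X)
  while (length(selected) < max_terms && length(remaining) > 0) {
    if (length(selected) == 0 && is.null(C)) {
      ## closed-form 2x2 screen (equals the GLM LRT with no covariates)
      lrt <- lrt_screen_2x2(X[, remaining, drop = FALSE], y)
      pv <- pchisq(lrt, df = 1, lower.tail = FALSE)
    } else {
      base <- cbind(1, X[, selected, drop = FALSE], C)
      f0 <- logit_fit(base, y)
      if (length(remaining) > 40) {
        ## rank all candidates by score test, then exact LRT on leaders
        stat <- score_screen(X[, remaining, drop = FALSE], y, base,
                             f0$mu)
        leaders <- order(stat, decreasing = TRUE)[seq_len(20)]
      } else leaders <- seq_along(remaining)
      pv <- rep(1, length(remaining))
      for (j in leaders) {
        f <- logit_fit(cbind(base, X[, remaining[j]]), y)
        pv[j] <- pchisq(max(0, f0$deviance - f$deviance), df = 1,
                        lower.tail = FALSE)
      }
    }
    best <- which.min(pv)
    if (pv[best] >= thresh) break
    sel_kmer <- remaining[best]
    cond <- paste(selected, collapse = ",")
    covs <- cbind(X[, selected, drop = FALSE], C)
    rec <- single_association(X[, sel_kmer], y,
                              covariates = if (ncol(covs)) covs else NULL,
                              kmer = sel_kmer,
                              position = positions[[sel_kmer]])
    rec$p <- pv[best]
    rec$conditioning <- cond
    records[[sel_kmer]] <- rec
    selected <- c(selected, sel_kmer)
    remaining <- setdiff(remaining, sel_kmer)
  }
  if (length(records) == 0) return(empty_assoc())
  out <- do.call(rbind, records)
  ## shadow collapse: correlated, position-overlapping unselected k-mers
  out$shadows <- ""
  if (length(remaining) > 0) {
    for (i in seq_len(nrow(out))) {
      r <- suppressWarnings(cor(X[, out$kmer[i]],
                                X[, remaining, drop = FALSE]))
      cand <- remaining[!is.na(r) & r > collapse_r]
      if (length(cand) && !is.na(out$position[i])) {
        pp <- positions[cand]
        cand <- cand[!is.na(pp) & pp < out$position[i] + k &
                       pp + k > out$position[i]]
      }
      out$shadows[i] <- paste(cand, collapse = ",")
    }
  }
  rownames(out) <- NULL
  class(out) <- c("AssociationRecord", "data.frame")
  out
}

empty_assoc <- function() {
  out <- data.frame(kmer = character(), position = numeric(),
                    beta = numeric(), se = numeric(), p = numeric(),
                    or = numeric(), separated = logical(),
                    conditioning = character(), shadows = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("AssociationRecord", "data.frame")
  out
}

#' Additive DNA-based score over selected motifs
#'
#' Scores each copy as the sum of selected log-odds ratios times presence,
#' bins copies into score deciles, and reports the per-bin outcome
#' frequency with binomial standard errors. The score is invariant to the
#' order of the selected records.
#'
#' @param selected An `AssociationRecord` set from [forward_selection()].
#' @param km A [kmer_presence_matrix()] result or 0/1 matrix covering the
#'   selected k-mers.
#' @param outcome Optional binary outcome for per-bin frequencies.
#' @return A list of class `AdditiveScore`: `score` (per copy), `bin`
#'   (decile assignment) and `bins` (per-bin n, mean outcome, se).
#' @export
additive_score <- function(selected, km, outcome = NULL) {
  if (nrow(selected) == 0) stop("no selected records")
  X <- if (inherits(km, "KmerMatrix")) km$X else km
  score <- drop(X[, selected$kmer, drop = FALSE] %*% selected$beta)
  if (length(unique(score)) == 1) {
    warning("all scores identical; single bin")
    bin <- rep(1L, length(score))
  } else {
    br <- unique(quantile(score, seq(0, 1, by = 0.1), names = FALSE))
    bin <- findInterval(score, br, left.open = TRUE,
                        rightmost.closed = TRUE) + 1L
    bin[score <= br[1]] <- 1L
    bin <- as.integer(factor(bin))        # compact bin ids
  }
  bins <- NULL
  if (!is.null(outcome)) {
    y <- as.numeric(outcome)
    bins <- do.call(rbind, lapply(sort(unique(bin)), function(bb) {
      sel <- bin == bb
      ph <- mean(y[sel])
      data.frame(bin = bb, n = sum(sel), mean_score = mean(score[sel]),
                 freq = ph, se = sqrt(ph * (1 - ph) / sum(sel)))
    }))
  }
  structure(list(score = score, bin = bin, bins = bins),
            class = "AdditiveScore")
}

#' Co-binding GLM: effect of each co-binding factor on hotspot odds
#'
#' For each factor with at least `min_instances` co-bound cases, fits a
#' logistic regression of the hotspot outcome on the binary co-binding
#' regressor and reports the effect as log2-odds with a 95% Wald CI
#' (natural-log estimates divided by `log(2)`).
#'
#' @param outcome Binary hotspot outcome at the anchor peaks.
#' @param cobound Named list (or matrix with named columns) of binary
#'   co-binding indicators, one per factor.
#' @param min_instances Minimum co-bound instances for a factor to be
#'   tested (default 30).
#' @return A data.frame: factor, n_cobound, log2_odds, lo, hi, p,
#'   separated. Excluded factors are absent from the result.
#' @export
cobinding_glm <- function(outcome, cobound, min_instances = 30) {
  if (is.matrix(cobound) || is.data.frame(cobound))
    cobound <- as.list(as.data.frame(cobound))
  y <- as.numeric(outcome)
  rows <- lapply(names(cobound), function(f) {
    x <- as.numeric(cobound[[f]])
    if (sum(x) < min_instances) return(NULL)
    rec <- single_association(x, y)
    z <- qnorm(0.975)
    data.frame(factor = f, n_cobound = sum(x),
               log2_odds = rec$beta / log(2),
               lo = (rec$beta - z * rec$se) / log(2),
               hi = (rec$beta + z * rec$se) / log(2),
               p = rec$p, separated = rec$separated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(factor = character(), n_cobound = integer(),
                      log2_odds = numeric(), lo = numeric(),
                      hi = numeric(), p = numeric(),
                      separated = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write association records as TSV
#' @param records An `AssociationRecord` data.frame.
#' @param path Output path.
#' @export
write_associations <- function(records, path) {
  write_header_tsv(as.data.frame(records), path)
}
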