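# The linear flexibility model: feature/target transforms, the published
# coefficients, fitting by ordinary least squares, and grouped
# cross-validation.
#
# Model: normalized RMSF_i = n + sum_k beta_k * O_ik, where O_ik are the
# log-transformed, per-protein standardized orbit counts. Both sides live in
# normalized log space, so predictions are rank-comparable within a protein
# but carry no absolute Angstrom scale.

#' RMSF profile constructor
#'
#' A per-atom fluctuation vector tagged as `raw` (positive Angstrom values,
#' e.g. from an ensemble or trajectory) or `normalized` (log-transformed and
#' per-protein z-scored, the space the linear model lives in).
#'
#' @param values numeric vector, one value per atom.
#' @param normalized logical flag.
#' @return Numeric vector of class `rmsf_profile` with attribute
#'   `normalized`.
#' @export
rmsf_profile <- function(values, normalized = FALSE) {
  structure(as.numeric(values), normalized = isTRUE(normalized),
            class = "rmsf_profile")
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' The published flexibility coefficients
#'
#' Intercept 0 and the 15 consensus regression coefficients for orbits
#' O0..O14, obtained by averaging ordinary-least-squares fits across three
#' independent molecular-dynamics replicates of a globular-protein training
#' set. With standardized target and features the intercept vanishes.
#'
#' @return Object of class `flex_model`: list with `intercept` and named
#'   `beta` vector of length 15.
#' @export
published_model <- function() {
  beta <- c(-1.91, -0.91, 2.98, 2.96, -0.92, -0.16, 0.12, -0.48,
            0.24, 0.31, 0.42, -0.78, 0.51, -1.73, -1.48)
  flex_model(0, beta)
}

#' Construct a flexibility model object
#'
#' @param intercept scalar intercept.
#' @param beta numeric vector of 15 orbit coefficients (order O0..O14).
#' @return Object of class `flex_model`.
#' @export
flex_model <- function(intercept, beta) {
  beta <- as.numeric(beta)
  if (length(beta) != 15 || any(!is.finite(beta)) || !is.finite(intercept))
    stop("a flexibility model needs a finite intercept and 15 finite betas")
  structure(list(intercept = as.numeric(intercept),
                 beta = setNames(beta, ORBIT_NAMES)),
            class = "flex_model")
}

#' @export
print.flex_model <- function(x, ...) {
  cat("GDV flexibility model (intercept ", format(x$intercept), ")\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

#' Transform orbit counts into model features
#'
#' Elementwise `log(1 + count)` followed by a per-column z-score within the
#' protein (sample standard deviation, n - 1). Columns with zero variance
#' map to all-zeros.
#'
#' @param gdv N x 15 orbit-count matrix, N >= 2.
#' @return N x 15 numeric feature matrix.
#' @export
transform_features <- function(gdv) {
  if (nrow(gdv) < 2) stop("need at least two atoms to standardize features")
  x <- log1p(as.matrix(gdv))
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  x <- sweep(x, 2, ctr)
  nz <- sds > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sds[nz], "/")
  x[, !nz] <- 0
  colnames(x) <- ORBIT_NAMES
  x
}

#' Transform a raw RMSF profile into the normalized model target
#'
#' Plain `log` (raw fluctuations are positive by construction) followed by a
#' per-protein z-score with sample standard deviation; a constant profile
#' maps to zeros.
#'
#' @param rmsf raw, strictly positive per-atom RMSF values.
#' @return Numeric vector of class `rmsf_profile`, flagged normalized.
#' @export
transform_target <- function(rmsf) {
  v <- as.numeric(rmsf)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("raw RMSF values must be finite and strictly positive")
  lv <- log(v)
  s <- sd(lv)
  out <- if (length(lv) < 2 || s == 0) rep(0, length(lv)) else (lv - mean(lv)) / s
  rmsf_profile(out, normalized = TRUE)
}

#' Predict normalized flexibility from features
#'
#' @param object a `flex_model`.
#' @param features N x 15 feature matrix from [transform_features()].
#' @param ... unused.
#' @return Numeric vector of class `rmsf_profile` (normalized): per atom,
#'   intercept + features . beta.
#' @export
predict.flex_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != 15)
    stop("feature matrix must have 15 columns, got ", ncol(features))
  rmsf_profile(drop(features %*% object$beta) + object$intercept,
               normalized = TRUE)
}

#' Assemble a training set entry
#'
#' @param id protein identifier.
#' @param gdv N x 15 orbit-count matrix.
#' @param rmsf reference [rmsf_profile()] (raw or normalized), length N.
#' @param ca_mask logical vector marking alpha-carbon rows.
#' @return List of class `flex_training_entry`.
#' @export
training_entry <- function(id, gdv, rmsf, ca_mask) {
  if (length(rmsf) != nrow(gdv) || length(ca_mask) != nrow(gdv))
    stop("entry '", id, "': GDV rows, RMSF length and Ca mask must align")
  structure(list(id = id, gdv = gdv, rmsf = rmsf, ca_mask = as.logical(ca_mask)),
            class = "flex_training_entry")
}

# Pooled design matrix and target across proteins.
pool_training <- function(train) {
  stopifnot(length(train) >= 1)
  xs <- lapply(train, function(e) transform_features(e$gdv))
  ys <- lapply(train, function(e) {
    if (is_normalized(e$rmsf)) as.numeric(e$rmsf) else
      as.numeric(transform_target(e$rmsf))
  })
  list(X = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       protein = rep(vapply(train, function(e) as.character(e$id),
                            character(1)),
                     vapply(xs, nrow, integer(1))))
}

#' Fit the flexibility model by ordinary least squares
#'
#' Applies the per-protein transforms, pools the rows of all proteins and
#' solves for the intercept plus 15 orbit coefficients. A rank-deficient
#' design is reported with a warning and solved by the minimum-norm
#' least-squares solution (singular-value pseudoinverse).
#'
#' @param train list of [training_entry()] objects; at least 16 pooled atoms.
#' @return A `flex_model`.
#' @export
fit_flex_model <- function(train) {
  pool <- pool_training(train)
  if (length(pool$y) < 16)
    stop("need at least 16 pooled atoms to fit 16 parameters")
  D <- cbind(`(Intercept)` = 1, pool$X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient design (rank ", qrD$rank, " of ", ncol(D),
            "); returning the minimum-norm least-squares solution")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% pool$y) / sv$d[pos])
    coef <- drop(coef)
  } else {
    coef <- qr.coef(qrD, pool$y)
  }
  flex_model(coef[1], coef[-1])
}

#' Grouped k-fold cross-validation
#'
#' Folds partition whole proteins (atoms of one protein never straddle the
#' train/test split): protein ids are shuffled with the given seed and dealt
#' round-robin into `k` folds. For each held-out protein the Spearman rank
#' correlation between predicted and reference values is computed on its
#' alpha-carbon atoms.
#'
#' @param train list of [training_entry()] objects, at least `k` of them.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return List with `scores` (data.frame: id, fold, rho, n_ca) and
#'   `mean_rho` (mean over proteins, NaN scores excluded).
#' @export
cross_validate <- function(train, k = 10L, seed = 1L) {
  n <- length(train)
  if (n < k) stop("fewer proteins (", n, ") than folds (", k, ")")
  ord <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  rows <- list()
  for (f in seq_len(k)) {
    held <- which(fold == f)
    model <- fit_flex_model(train[-held])
    for (i in held) {
      e <- train[[i]]
      pred <- predict(model, transform_features(e$gdv))
      ref <- if (is_normalized(e$rmsf)) as.numeric(e$rmsf) else
        as.numeric(transform_target(e$rmsf))
      rho <- spearman_ca(pred, ref, e$ca_mask)
      rows[[length(rows) + 1L]] <- data.frame(
        id = as.character(e$id), fold = f, rho = rho, n_ca = sum(e$ca_mask))
    }
  }
  scores <- do.call(rbind, rows)
  list(scores = scores, mean_rho = mean(scores$rho, na.rm = TRUE))
}

#' Serialize a flexibility model to JSON
#'
#' The document records the coefficients together with the transform
#' conventions they assume (log offsets and sample standard deviation).
#'
#' @param model a `flex_model`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_flex_model <- function(model, path) {
  doc <- list(
    intercept = model$intercept,
    betas = unname(model$beta),
    orbit_order = ORBIT_NAMES,
    transform = list(log_offset_features = 1, log_offset_target = 0,
                     sd = "sample")
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flexibility model from JSON
#'
#' @param path path to a file written by [write_flex_model()].
#' @return A `flex_model`.
#' @export
read_flex_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(doc$orbit_order), ORBIT_NAMES))
    stop("model file does not use the canonical orbit order O0..O14")
  flex_model(doc$intercept, doc$betas)
}
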