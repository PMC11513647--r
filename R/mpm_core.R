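#' @keywords internal
"_PACKAGE"

# decomposition / survival-sum tolerance: published MPMs carry <= 6 significant
# digits, so anything beyond 1e-9 is a data error, not rounding
.mpm_tol <- 1e-9

#' The five ordered levels of the sociality continuum
#'
#' Returns the levels of the sociality continuum in increasing order of the
#' spatial, temporal and qualitative intensity of conspecific interactions:
#' solitary, gregarious, communal, colonial, social.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' sociality_levels()
sociality_levels <- function() {
  c("solitary", "gregarious", "communal", "colonial", "social")
}

#' Coerce to an ordered sociality factor
#'
#' @param x Character, integer (0--4) or factor codes.
#' @return An ordered factor with the five canonical levels.
#' @export
as_sociality <- function(x) {
  lv <- sociality_levels()
  if (is.numeric(x)) {
    stopifnot(all(x %in% 0:4))
    x <- lv[x + 1L]
  }
  x <- as.character(x)
  if (!all(x %in% lv)) {
    stop("unknown sociality level(s): ", paste(setdiff(x, lv), collapse = ", "))
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Validate and construct a matrix population model
#'
#' Builds an MPM object from its survival/transition sub-matrix `matU` and
#' reproduction sub-matrix `matF`, enforcing the structural invariants:
#' all matrices square, same dimension, nonnegative; `matA = matU + matF`
#' within tolerance; every column sum of `matU` (stage-specific survival)
#' at most 1. Columns index the source stage and rows the destination stage,
#' so `A[i, j]` is the per-capita contribution of stage `j` to stage `i`
#' over one projection interval.
#'
#' @param matU Square nonnegative survival/transition sub-matrix.
#' @param matF Square nonnegative reproduction sub-matrix.
#' @param matA Optional full projection matrix; defaults to `matU + matF` and
#'   is checked against that sum when supplied.
#' @param P Projection interval in years (positive).
#' @param stage_labels Optional character vector of stage names, in
#'   developmental order.
#' @param species_id Species identifier.
#' @param treatment,captive,extant Study metadata flags: experimentally
#'   manipulated population, captive population, extant species.
#' @param study_duration Optional study length in years (metadata used by
#'   [select_study()]).
#' @param tol Numerical tolerance for the decomposition and survival checks.
#' @return An object of class `mpm`.
#' @export
#' @examples
#' validate_mpm(matU = matrix(c(0, 0.5, 0, 0), 2),
#'              matF = matrix(c(0, 0, 2, 0), 2))
validate_mpm <- function(matU, matF, matA = NULL, P = 1,
                         stage_labels = NULL, species_id = NA_character_,
                         treatment = FALSE, captive = FALSE, extant = TRUE,
                         study_duration = NA_real_, tol = .mpm_tol) {
  matU <- as.matrix(matU)
  matF <- as.matrix(matF)
  if (nrow(matU) != ncol(matU)) stop("matU is not square")
  if (nrow(matF) != ncol(matF)) stop("matF is not square")
  if (nrow(matU) != nrow(matF)) {
    stop("dimension mismatch: matU is ", nrow(matU), "x", ncol(matU),
         ", matF is ", nrow(matF), "x", ncol(matF))
  }
  if (!is.null(matA)) {
    matA <- as.matrix(matA)
    if (!all(dim(matA) == dim(matU))) stop("dimension mismatch for matA")
    if (max(abs(matA - (matU + matF))) > tol) {
      stop("decomposition error: matA differs from matU + matF beyond tolerance")
    }
  } else {
    matA <- matU + matF
  }
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0) {
    stop("projection interval P must be a positive number")
  }
  if (any(matU < 0) || any(matF < 0) || any(matA < 0)) {
    stop("negative entry in matrix population model")
  }
  cs <- colSums(matU)
  if (any(cs > 1 + tol)) {
    bad <- which(cs > 1 + tol)
    stop("survival exceeds 1 in stage(s) ", paste(bad, collapse = ", "),
         " (column sums ", paste(signif(cs[bad], 6), collapse = ", "), ")")
  }
  n <- nrow(matU)
  if (is.null(stage_labels)) stage_labels <- paste0("stage_", seq_len(n))
  if (length(stage_labels) != n) stop("stage_labels length mismatch")
  dimnames(matA) <- dimnames(matU) <- dimnames(matF) <-
    list(stage_labels, stage_labels)
  structure(
    list(matA = matA, matU = matU, matF = matF, P = P,
         stage_labels = as.character(stage_labels),
         species_id = species_id,
         treatment = isTRUE(treatment), captive = isTRUE(captive),
         extant = isTRUE(extant), study_duration = study_duration),
    class = "mpm"
  )
}

#' @export
print.mpm <- function(x, ...) {
  cat("Matrix population model",
      if (!is.na(x$species_id)) paste0("[", x$species_id, "]"), "\n")
  cat("  dimension:", nrow(x$matA), "stages; projection interval P =",
      x$P, "year(s)\n")
  cat("  A = U + F; column survival sums:",
      paste(signif(colSums(x$matU), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mpm <- function(x) dim(x$matA)

#' Apply the study-selection criteria to a set of species records
#'
#' Retains records satisfying, in order: (i) unmanipulated and wild
#' (not captive, not experimentally treated); (ii) matrix dimension at least
#' 4; (iii) survival/reproduction split available (`matU`/`matF` present);
#' (iv) stage-specific survival column sums at most 1; (v) extant species.
#' Rejected records are logged with the first violated criterion.
#'
#' @param records List of species records, each a list with at least an
#'   `mpm` element (class `mpm`, or `NULL` when no U/F split exists).
#' @param min_dim Minimum matrix dimension (default 4).
#' @return A list with elements `retained` (the surviving records) and
#'   `rejection_log` (data frame with columns `species_id`, `reason`).
#' @export
select_mpms <- function(records, min_dim = 4L) {
  reasons <- character(0)
  ids <- character(0)
  keep <- logical(length(records))
  for (k in seq_along(records)) {
    r <- records[[k]]
    m <- r$mpm
    id <- if (!is.null(m) && !is.na(m$species_id)) m$species_id
          else if (!is.null(r$species_id)) r$species_id else paste0("record_", k)
    reason <- NULL
    if (is.null(m)) {
      reason <- "no U/F split"
    } else if (m$captive || m$treatment) {
      reason <- "wild/unmanipulated"
    } else if (nrow(m$matA) < min_dim) {
      reason <- "dimension"
    } else if (is.null(m$matU) || is.null(m$matF)) {
      reason <- "no U/F split"
    } else if (any(colSums(m$matU) > 1 + .mpm_tol)) {
      reason <- "survival > 1"
    } else if (!m$extant) {
      reason <- "extinct"
    }
    if (is.null(reason)) {
      keep[k] <- TRUE
    } else {
      ids <- c(ids, id)
      reasons <- c(reasons, reason)
    }
  }
  list(retained = records[keep],
       rejection_log = data.frame(species_id = ids, reason = reasons,
                                  stringsAsFactors = FALSE))
}

#' Pick the most representative study per species
#'
#' When several studies exist for one species, retains the study with the
#' longest duration, breaking ties by greatest matrix dimension, then by
#' input order. This is the cross-study metadata filter applied before
#' [grand_mean()]; it never averages across studies.
#'
#' @param records List of species records (same species).
#' @return The single chosen record.
#' @export
select_study <- function(records) {
  stopifnot(length(records) >= 1L)
  dur <- vapply(records, function(r) {
    d <- r$mpm$study_duration
    if (is.null(d) || is.na(d)) -Inf else d
  }, numeric(1))
  dm <- vapply(records, function(r) nrow(r$mpm$matA), numeric(1))
  records[[order(-dur, -dm, seq_along(records))[1L]]]
}

#' Rescale a matrix population model to an annual projection interval
#'
#' Raises every element of `A`, `U` and `F` to the power `1/P` so that all
#' derived demographic traits share annual time units; the rescaled model
#' has `P = 1`. The operation is the identity when `P = 1`, hence idempotent.
#'
#' @param mpm An object of class `mpm`.
#' @return The annualized `mpm`.
#' @export
rescale_to_annual <- function(mpm) {
  stopifnot(inherits(mpm, "mpm"))
  if (mpm$P == 1) return(mpm)
  e <- 1 / mpm$P
  validate_mpm(matU = mpm$matU^e, matF = mpm$matF^e, P = 1,
               stage_labels = mpm$stage_labels, species_id = mpm$species_id,
               treatment = mpm$treatment, captive = mpm$captive,
               extant = mpm$extant, study_duration = mpm$study_duration)
}

#' Element-by-element arithmetic grand mean of matrix population models
#'
#' Averages `U` and `F` (hence `A`) element-wise over the matrices supplied
#' for one species. All inputs must share dimension, stage labels and
#' projection interval.
#'
#' @param mpms List of `mpm` objects.
#' @return A single `mpm` with the element-wise mean matrices.
#' @export
grand_mean <- function(mpms) {
  stopifnot(length(mpms) >= 1L, all(vapply(mpms, inherits, TRUE, "mpm")))
  d <- vapply(mpms, function(m) nrow(m$matA), integer(1))
  if (length(unique(d)) != 1L) stop("dimension mismatch across MPMs")
  labs <- lapply(mpms, `[[`, "stage_labels")
  if (length(unique(vapply(labs, paste, "", collapse = "\r"))) != 1L) {
    stop("stage label mismatch across MPMs")
  }
  Ps <- vapply(mpms, `[[`, numeric(1), "P")
  if (length(unique(Ps)) != 1L) stop("projection interval mismatch across MPMs")
  mU <- Reduce(`+`, lapply(mpms, `[[`, "matU")) / length(mpms)
  mF <- Reduce(`+`, lapply(mpms, `[[`, "matF")) / length(mpms)
  m1 <- mpms[[1L]]
  validate_mpm(matU = mU, matF = mF, P = Ps[1L], stage_labels = m1$stage_labels,
               species_id = m1$species_id, treatment = m1$treatment,
               captive = m1$captive, extant = m1$extant,
               study_duration = m1$study_duration)
}

# boolean reachability closure of (I | B) by repeated squaring
.reach <- function(B) {
  n <- nrow(B)
  M <- B | diag(TRUE, n)
  steps <- ceiling(log2(max(n, 2)))
  for (k in seq_len(steps)) M <- (M %*% M) > 0
  M
}

#' Irreducibility, primitivity and ergodicity of a projection matrix
#'
#' Irreducible: the life-cycle digraph of positive entries is strongly
#' connected. Primitive: irreducible and aperiodic, tested with Wielandt's
#' bound (`A^(n^2 - 2n + 2)` strictly positive). Ergodic: the left
#' eigenvector associated with the dominant eigenvalue is strictly positive,
#' so the stable structure is reached from any nonnegative initial
#' condition. Elasticities and asymptotic/transient metrics are only
#' defined for matrices passing all three.
#'
#' @param A Square nonnegative matrix (or an `mpm`, whose `matA` is used).
#' @param tol Entries at or below `tol` count as structural zeros.
#' @return List with logical elements `irreducible`, `primitive`, `ergodic`.
#' @export
#' @examples
#' check_ergodicity(matrix(c(1, 0.5, 2, 0), 2))  # primitive Leslie matrix
check_ergodicity <- function(A, tol = 1e-12) {
  if (inherits(A, "mpm")) A <- A$matA
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(n == ncol(A), all(A >= 0))
  B <- A > tol
  irreducible <- all(.reach(B))
  primitive <- FALSE
  if (irreducible) {
    if (n == 1L) {
      primitive <- B[1L, 1L]
    } else {
      expo <- n^2 - 2L * n + 2L
      Pw <- B
      k <- 1L
      while (k < expo && !all(Pw)) {
        Pw <- (Pw %*% B) > 0
        k <- k + 1L
      }
      primitive <- all(Pw)
    }
  }
  ev <- eigen(t(A))
  i1 <- which.max(Mod(ev$values))
  v <- ev$vectors[, i1]
  v <- Re(v / v[which.max(Mod(v))])
  ergodic <- all(v > tol) && abs(Im(ev$values[i1])) < 1e-10
  list(irreducible = irreducible, primitive = primitive, ergodic = ergodic)
}

#' Does a matrix pass the eigen-structure gate?
#'
#' `TRUE` when the matrix is irreducible, primitive and ergodic, which
#' guarantees a single real dominant eigenvalue.
#'
#' @inheritParams check_ergodicity
#' @return Logical scalar.
#' @export
passes_gate <- function(A, tol = 1e-12) {
  g <- check_ergodicity(A, tol)
  g$irreducible && g$primitive && g$ergodic
}
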