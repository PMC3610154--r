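#' Experiment data model
#'
#' A structured container for measurements of substances (metabolites,
#' enzyme activities, morphological parameters, genes) across experimental
#' conditions (species/genotype/ecotype/treatment), time points and
#' replicates, plus per-substance meta-data.  Internally a substances x
#' samples matrix with \code{NA} for absent measurements — missing cells are
#' never imputed; downstream statistics use pairwise-complete observations.
#'
#' @param substances data frame with columns \code{name} (unique, non-empty),
#'   \code{kind} (one of metabolite, enzyme, morphological, gene, other) and
#'   \code{unit}; an optional \code{alt_ids} column holds "|"-joined synonym
#'   strings.
#' @param samples data frame with columns \code{condition}, \code{time},
#'   \code{time_unit}, \code{replicate}; the (condition, time, replicate)
#'   triple must be unique.
#' @param values numeric matrix, \code{nrow(substances)} x
#'   \code{nrow(samples)}; \code{NA} = absent measurement.
#' @param meta named list of experiment-level meta-data (\code{name},
#'   \code{coordinator}, ...).
#' @return an object of class \code{omic_experiment}.
#' @export
experiment <- function(substances, samples, values, meta = list()) {
  substances <- as.data.frame(substances, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("name", "kind", "unit") %in% names(substances)))
    stop2("substances needs columns name, kind, unit")
  if (is.null(substances$alt_ids)) substances$alt_ids <- ""
  if (any(!nzchar(substances$name))) stop2("substance names must be non-empty")
  if (anyDuplicated(substances$name))
    stop2("duplicate substance names: ",
          paste(unique(substances$name[duplicated(substances$name)]), collapse = ", "))
  bad <- setdiff(unique(substances$kind),
                 c("metabolite", "enzyme", "morphological", "gene", "other"))
  if (length(bad)) stop2("unknown substance kind(s): ", paste(bad, collapse = ", "))
  need <- c("condition", "time", "time_unit", "replicate")
  if (!all(need %in% names(samples))) stop2("samples needs columns ", paste(need, collapse = ", "))
  key <- paste(samples$condition, samples$time, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop2("replicate indices must be unique within (condition, time)")
  values <- as.matrix(values)
  if (!is.numeric(values)) storage.mode(values) <- "double"
  if (nrow(values) != nrow(substances) || ncol(values) != nrow(samples))
    stop2("values must be |substances| x |samples|")
  dimnames(values) <- NULL
  structure(list(substances = substances, samples = samples,
                 values = values, meta = meta),
            class = "omic_experiment")
}

#' @export
print.omic_experiment <- function(x, ...) {
  cat(sprintf(paste0("<omic_experiment '%s': %d substances, %d conditions, ",
                     "%d samples, %d measurements>\n"),
              x$meta$name %||% "?", nrow(x$substances),
              length(unique(x$samples$condition)), nrow(x$samples),
              sum(!is.na(x$values))))
  invisible(x)
}

exp_is <- function(e) inherits(e, "omic_experiment")

#' Counts and accessors
#' @param e an \code{omic_experiment}. @param kind optional substance kind filter.
#' @export
exp_substances <- function(e, kind = NULL) {
  stopifnot(exp_is(e))
  if (is.null(kind)) e$substances$name
  else e$substances$name[e$substances$kind %in% kind]
}

#' @rdname exp_substances
#' @export
exp_conditions <- function(e) unique(e$samples$condition)

#' @rdname exp_substances
#' @export
exp_measurement_count <- function(e) sum(!is.na(e$values))

#' Substance synonyms as a character vector
#' @param e experiment. @param substance substance name.
#' @export
exp_alt_ids <- function(e, substance) {
  i <- match(substance, e$substances$name)
  if (is.na(i)) stop2("unknown substance: ", substance)
  v <- e$substances$alt_ids[i]
  if (!nzchar(v)) character() else strsplit(v, "|", fixed = TRUE)[[1]]
}

#' Replicate summary statistics
#'
#' For one substance under one condition, per time point: the number of
#' present replicate values, their mean, standard deviation and standard
#' error.  With a single value the dispersion statistics are reported absent
#' (\code{NA}); with none, so is the mean.
#'
#' @param e experiment. @param substance substance name.
#' @param condition condition name.
#' @return data frame with columns \code{time}, \code{time_unit}, \code{n},
#'   \code{mean}, \code{sd}, \code{sem}.
#' @export
summarize_experiment <- function(e, substance, condition) {
  stopifnot(exp_is(e))
  si <- match(substance, e$substances$name)
  if (is.na(si)) stop2("unknown substance: ", substance)
  if (!(condition %in% e$samples$condition)) stop2("unknown condition: ", condition)
  sel <- e$samples$condition == condition
  times <- unique(e$samples[sel, c("time", "time_unit")])
  res <- lapply(seq_len(nrow(times)), function(k) {
    cols <- which(sel & e$samples$time == times$time[k] &
                  e$samples$time_unit == times$time_unit[k])
    v <- e$values[si, cols]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(time = times$time[k], time_unit = times$time_unit[k], n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               sd = if (n > 1) stats::sd(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  })
  do.call(rbind, res)
}

#' Per-condition replicate-mean profile matrix
#'
#' Collapses the measurement tensor to one value per (substance, condition):
#' the mean over all present replicates and time points.  This is the
#' profile representation used by the correlation and clustering modules,
#' where the observation axis is the condition panel (e.g. ecotypes).
#'
#' @param e experiment.
#' @return numeric matrix substances x conditions with NA where a substance
#'   was never measured under a condition.
#' @export
exp_profiles <- function(e) {
  stopifnot(exp_is(e))
  conds <- exp_conditions(e)
  out <- matrix(NA_real_, nrow(e$substances), length(conds),
                dimnames = list(e$substances$name, conds))
  for (j in seq_along(conds)) {
    cols <- which(e$samples$condition == conds[j])
    block <- e$values[, cols, drop = FALSE]
    m <- rowMeans(block, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    out[, j] <- m
  }
  out
}

#' Structural equality of two experiments
#' @param a,b experiments. @param tol numeric tolerance on values.
#' @export
exp_identical <- function(a, b, tol = 1e-9) {
  stopifnot(exp_is(a), exp_is(b))
  if (!identical(dim(a$values), dim(b$values))) return(FALSE)
  # align substance and sample order
  so <- match(a$substances$name, b$substances$name)
  if (anyNA(so)) return(FALSE)
  akey <- paste(a$samples$condition, a$samples$time, a$samples$replicate, sep = "\r")
  bkey <- paste(b$samples$condition, b$samples$time, b$samples$replicate, sep = "\r")
  co <- match(akey, bkey)
  if (anyNA(co)) return(FALSE)
  bs <- b$substances[so, ]
  if (!identical(a$substances$kind, bs$kind) || !identical(a$substances$unit, bs$unit))
    return(FALSE)
  va <- a$values; vb <- b$values[so, co, drop = FALSE]
  same_na <- identical(is.na(va), is.na(vb))
  same_na && all(abs(va[!is.na(va)] - vb[!is.na(vb)]) <= tol)
}
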