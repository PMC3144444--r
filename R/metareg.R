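#' Specification of the accuracy meta-model
#'
#' The linear model relating validation accuracy to trait heritability,
#' the proportion of null SNP (pi) and the validation generation:
#' intercept plus `{h2, pi, generation, generation^2, h2 x generation,
#' pi x generation}` — seven coefficients.  Dropping the pi terms (an
#' option, since most methods do not estimate pi) is equivalent to
#' fitting the average pi.
#'
#' @param include_pi_terms Include `pi` and `pi x generation`?  When they
#'   are included, accuracies from pedigree-based methods are excluded
#'   from the fit, because they are not expected to depend on pi.
#' @param method_factor Also fit the estimation method as a factor
#'   (default `FALSE`).
#' @return list of class `accuracy_model_spec` with the ordered regressor
#'   labels.
#' @export
accuracy_model_spec <- function(include_pi_terms = TRUE,
                                method_factor = FALSE) {
  regressors <- c("h2", "generation", "generation_squared",
                  "h2_x_generation")
  if (include_pi_terms)
    regressors <- c("h2", "pi", "generation", "generation_squared",
                    "h2_x_generation", "pi_x_generation")
  structure(list(regressors = regressors,
                 include_pi_terms = include_pi_terms,
                 method_factor = method_factor),
            class = "accuracy_model_spec")
}

#' Fit the linear meta-model for accuracy
#'
#' Ordinary least squares of accuracy on heritability, pi and generation
#' terms, with t-based p-values.  Records must supply one row per
#' method-by-trait-by-generation accuracy with columns `accuracy`, `h2`,
#' `generation` and (if pi terms are included) `pi`; a `method` column is
#' used to exclude pedigree-based rows when pi terms are present and to
#' fit the optional method factor.
#'
#' @param records Accuracy table (e.g. from [run_design()] joined with
#'   per-trait `h2` and `pi` estimates).
#' @param spec An [accuracy_model_spec()].
#' @return Object of class `gs_metafit`: `coefficients` (estimate, se,
#'   t, p), the underlying `lm` fit, the model data and the spec.
#' @export
fit_accuracy_model <- function(records, spec = accuracy_model_spec()) {
  df <- as.data.frame(records)
  if (!"generation" %in% names(df) &&
      "validation_generation" %in% names(df))
    df$generation <- df$validation_generation
  need <- c("accuracy", "h2", "generation",
            if (spec$include_pi_terms) "pi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (spec$include_pi_terms && "method" %in% names(df)) {
    df <- df[!grepl("^P", df$method), , drop = FALSE] # drop pedigree-based
  }
  df <- df[!is.na(df$accuracy), , drop = FALSE]

  terms <- c("h2", "generation", "I(generation^2)", "h2:generation")
  if (spec$include_pi_terms)
    terms <- c(terms, "pi", "pi:generation")
  if (spec$method_factor) terms <- c(terms, "method")
  form <- stats::reformulate(terms, response = "accuracy")

  if (nrow(df) < length(terms) + 3)
    stop("need at least ", length(terms) + 3, " accuracy records")
  mm <- model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop("collinear design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm(form, data = df)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, lm = fit, data = df, spec = spec),
            class = "gs_metafit")
}

#' @export
print.gs_metafit <- function(x, ...) {
  cat("Accuracy meta-model (OLS)\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Least-squares means of accuracy on a grid
#'
#' Predicted accuracy at user-supplied values of pi, h2 and generation —
#' e.g. accuracy over generations for traits with low versus high pi at
#' h2 = 0.5.  Model terms not pinned down by the grid are held at their
#' means in the fitted data (the method factor, when present, is averaged
#' over); in particular, with no grid at all the prediction equals the
#' grand mean of the fitted values.
#'
#' @param fit A `gs_metafit`.
#' @param pi,h2,generation Grid values; any left `NULL` keeps the
#'   corresponding model terms at their data means.  A warning is issued
#'   for values outside the observed range.
#' @return data.frame of grid points with the predicted `accuracy`.
#' @export
ls_means <- function(fit, pi = NULL, h2 = NULL, generation = NULL) {
  df <- fit$data
  given <- list(pi = pi, h2 = h2, generation = generation)
  for (nm in names(given)) {
    v <- given[[nm]]
    if (!is.null(v) && nm %in% names(df) &&
        (min(v) < min(df[[nm]]) || max(v) > max(df[[nm]])))
      warning(nm, " grid extends beyond the observed range")
  }
  vals <- given[!vapply(given, is.null, logical(1))]
  grid <- if (length(vals)) expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)

  mm <- model.matrix(fit$lm)
  col_means <- colMeans(mm)
  beta <- coef(fit$lm)

  ## value of one multiplicative term component at a grid point
  component_value <- function(comp, point) {
    if (comp == "(Intercept)") return(1)
    if (comp %in% names(point)) return(point[[comp]])
    if (comp == "I(generation^2)" && "generation" %in% names(point))
      return(point[["generation"]]^2)
    NA_real_ # not determined by the grid -> use the column mean
  }
  grid$accuracy <- vapply(seq_len(max(nrow(grid), 1)), function(i) {
    point <- if (ncol(grid)) as.list(grid[i, , drop = FALSE]) else list()
    val <- vapply(names(beta), function(term) {
      comps <- strsplit(term, ":", fixed = TRUE)[[1]]
      parts <- vapply(comps, component_value, numeric(1), point = point)
      if (anyNA(parts)) {
        known <- prod(parts[!is.na(parts)])
        ## unresolved factors enter at the mean of their (partial) column;
        ## when nothing is resolved this is just the model-matrix mean
        if (all(is.na(parts))) col_means[[term]]
        else known * mean_unresolved(df, comps[is.na(parts)])
      } else prod(parts)
    }, numeric(1))
    sum(beta * val)
  }, numeric(1))
  grid
}

## mean of the product of unresolved term components over the fitted data
mean_unresolved <- function(df, comps) {
  cols <- lapply(comps, function(comp) {
    if (comp == "I(generation^2)") return(df$generation^2)
    if (comp %in% names(df)) return(df[[comp]])
    if (grepl("^method", comp)) # dummy column of the method factor
      return(as.numeric(df$method == sub("^method", "", comp)))
    stop("cannot resolve model term component: ", comp)
  })
  mean(Reduce(`*`, cols))
}
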