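# Parameter and data file I/O, reference parameter sets, and the three
# packaged workflows.

#' Save / load parameter sets as schema-versioned JSON
#'
#' Parameter files are flat JSON maps under a `params` field with
#' `schema_version` and `model` fields (`"isn"`, `"population"` or
#' `"mtorc1_submodel"`).  Loading validates the schema, rejects unknown
#' parameter names (naming them), rebuilds the object through its
#' constructor and therefore re-checks every invariant.
#'
#' @param params an [isn_params()], [pop_params()] or [mtorc1_params()]
#'   object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the reconstructed object.
#' @export
write_params <- function(params, path) {
  model <- switch(class(params)[1],
                  isn_params = "isn", pop_params = "population",
                  mtorc1_params = "mtorc1_submodel",
                  stop("unsupported parameter class: ", class(params)[1]))
  store <- unclass(params)
  if (model == "isn") store <- store[setdiff(names(store), c("a0", "a1", "ab"))]
  jsonlite::write_json(list(schema_version = "1", model = model,
                            params = store),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || is.null(obj$model) || is.null(obj$params))
    stop("not a parameter file (needs schema_version, model, params)")
  pars <- as.list(obj$params)
  ctor <- switch(obj$model,
                 isn = isn_params, population = pop_params,
                 mtorc1_submodel = mtorc1_params,
                 stop("unknown model type: ", obj$model))
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(pars), allowed)
  if (length(unknown))
    stop("unknown parameter name(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(ctor, pars)
}

#' Read ISN parameter sets from a parameter-by-condition CSV table
#'
#' Reads a table laid out with one row per parameter and one column per
#' condition / cell line (first column `parameter`), returning one
#' validated [isn_params()] set per condition column.  A `gsk3b_substrate`
#' row, if present, holds the string variants.
#'
#' @param path CSV file path.
#' @return named list of `isn_params` objects, one per condition column.
#' @export
read_params_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "parameter") stop("first column must be 'parameter'")
  conds <- names(tab)[-1]
  allowed <- names(formals(isn_params))
  unknown <- setdiff(tab$parameter, allowed)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  out <- lapply(conds, function(cn) {
    vals <- stats::setNames(as.list(tab[[cn]]), tab$parameter)
    num <- setdiff(names(vals), "gsk3b_substrate")
    vals[num] <- lapply(vals[num], as.numeric)
    do.call(isn_params, vals)
  })
  stats::setNames(out, conds)
}

#' Read / write dose-response measurement tables
#'
#' CSV with columns `condition`, `analyte`, `insulin_nM`, `value`, and
#' optionally `error`, `used_in_fit`.
#'
#' @param data a measurement table (data frame).
#' @param path CSV file path.
#' @return `read_measurements()` returns the checked data frame.
#' @export
write_measurements <- function(data, path) {
  utils::write.csv(check_measurement_table(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  check_measurement_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged reference parameter sets
#'
#' Returns the package's synthetic reference parameter sets.  These are
#' constructed sets (no experimental estimates are redistributed): they are
#' calibrated so that the model reproduces characteristic published
#' observables of each system -- the myoblast set (`"c2c12"`) a weak
#' maximal Akt response (total phospho-Akt a few percent of total Akt at
#' 100 nM insulin) with about half of GLUT4 at the surface, and the myotube
#' set (`"l6"`) a strong response (total phospho-Akt close to 80 percent)
#' -- see the package vignette for the construction.
#'
#' @param which `"c2c12"` (myoblast-like) or `"l6"` (myotube-like).
#' @return an `isn_params` object.
#' @export
isn_reference_params <- function(which = c("c2c12", "l6")) {
  which <- match.arg(which)
  read_params(system.file("extdata",
                          paste0("isn_params_", which, "_synthetic.json"),
                          package = "isnet", mustWork = TRUE))
}

#' @rdname isn_reference_params
#' @return `mtorc1_reference_params()`: an `mtorc1_params` object.
#' @export
mtorc1_reference_params <- function() {
  read_params(system.file("extdata", "mtorc1_submodel_synthetic.json",
                          package = "isnet", mustWork = TRUE))
}

#' @rdname isn_reference_params
#' @return `pop_reference_params()`: named list of `pop_params` per dose
#'   (nM) of a dual mTOR inhibitor, for an AML-like line.
#' @export
pop_reference_params <- function() {
  tab <- utils::read.csv(system.file("extdata", "pop_params_aml_synthetic.csv",
                                     package = "isnet", mustWork = TRUE))
  out <- lapply(seq_len(nrow(tab)), function(i)
    pop_params(lambda1 = tab$lambda1[i], T2 = tab$T2[i], T3 = tab$T3[i],
               mu_p = tab$mu_p[i], mu_pp = tab$mu_pp[i],
               mu_deg = tab$mu_deg[i], Delta = tab$Delta[i]))
  stats::setNames(out, tab$dose)
}

#' Run a packaged analysis workflow
#'
#' Deterministic end-to-end pipelines tying the stages together:
#' \describe{
#'   \item{muscle_fit}{generate (or load) a two-condition dose-response
#'     table, fit the shared ISN parameters, report loss and curve-recovery
#'     RMSE, and compute the sensitivity matrix at the half-response
#'     insulin level.}
#'   \item{extension_sim}{solve the extended network (TSC2/Rheb/PRAS40
#'     submodel) under every named perturbation and tabulate the states.}
#'   \item{aml_drug}{generate (or load) per-dose population observations,
#'     fit the population model per dose, refit the network inhibition
#'     multipliers against the phospho-S6K1 profile at the equivalent
#'     insulin level, and fit the saturating link functions.}
#' }
#'
#' @param name workflow name.
#' @param config list of options; unset entries use packaged defaults.
#'   Common: `seed` (integer), `output_dir` (optional; CSV outputs are
#'   written there).  `muscle_fit`: `params`, `free`, `sd`, `n_starts`.
#'   `extension_sim`: `params`, `sub`, `insulin`.  `aml_drug`: `params`,
#'   `pop_truth`, `sd`, `Ie_equiv`.
#' @return a named list of results (the "report bundle"); identical across
#'   reruns with the same config.
#' @export
run_workflow <- function(name = c("muscle_fit", "extension_sim", "aml_drug"),
                         config = list()) {
  name <- match.arg(name)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- config$output_dir
  save_csv <- function(df, file) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      utils::write.csv(df, file.path(outdir, file), row.names = FALSE)
    }
  }
  if (name == "muscle_fit") {
    params <- if (is.null(config$params)) isn_reference_params("c2c12")
              else config$params
    sd <- if (is.null(config$sd)) 0.03 else config$sd
    free <- if (is.null(config$free)) c("a3", "a6", "a9", "a24") else config$free
    tab <- if (is.null(config$data))
      synth_dose_response(params, sd = sd, seed = seed) else config$data
    start <- params
    if (!is.null(config$start)) start <- config$start
    fit <- isn_fit(tab, start, free = free,
                   conditions = list(control = "control",
                                     pten_silenced = "pten_silenced"),
                   n_starts = if (is.null(config$n_starts)) 1 else config$n_starts,
                   seed = seed)
    truth <- attr(tab, "truth")
    rmse <- NA_real_
    if (!is.null(truth)) {
      pred <- predict(fit, insulin = sort(unique(truth$insulin_nM)))
      m <- merge(truth, pred, by = c("condition", "analyte", "insulin_nM"),
                 suffixes = c(".true", ".fit"))
      rmse <- sqrt(mean((m$value.true - m$value.fit)^2))
    }
    sens <- isn_sensitivity(fit$params, fit$env, Ie = fit$params$Ie_half)
    save_csv(fit$data, "muscle_fit_data.csv")
    save_csv(as.data.frame(unclass(sens)[, ]), "muscle_fit_sensitivity.csv")
    list(fit = fit, curve_recovery_rmse = rmse, sensitivity = sens)
  } else if (name == "extension_sim") {
    params <- if (is.null(config$params)) isn_reference_params("l6")
              else config$params
    sub <- if (is.null(config$sub)) mtorc1_reference_params() else config$sub
    env <- isn_environment()
    perturbations <- c("control", names(mtor_perturbations))
    states <- lapply(perturbations, function(nm)
      simulate_perturbation(params, env, sub, nm,
                            Ie = config$insulin))
    tab <- do.call(rbind, lapply(seq_along(perturbations), function(i) {
      st <- states[[i]]
      data.frame(perturbation = perturbations[i], Ie_nM = attr(st, "Ie"),
                 mTORC1n = st$mTORC1n, S6K1n = st$S6K1n,
                 mTORC2n = st$mTORC2n, AktnS = st$AktnS,
                 AktnT = st$AktnT, AktnTS = st$AktnTS,
                 RhebGTPn = attr(st, "submodel")$RhebGTPn,
                 PRAS40n = attr(st, "submodel")$PRAS40n)
    }))
    save_csv(tab, "extension_sim.csv")
    list(table = tab, states = stats::setNames(states, perturbations))
  } else {
    params <- if (is.null(config$params)) isn_reference_params("l6")
              else config$params
    truth <- if (is.null(config$pop_truth)) pop_reference_params()
             else config$pop_truth
    sd <- if (is.null(config$sd)) 0.01 else config$sd
    synth <- synth_population(truth, sd = sd, seed = seed)
    alpha_control <- truth[["0"]]$alpha
    pfit <- cellpop_fit(synth$data, alpha_control = alpha_control,
                        seed = seed)
    est <- coef(pfit)
    # normalized pS6K1 profile used as the drug read-out for the refit:
    # saturating decay in dose
    doses <- est$dose
    s6k1_ratio <- if (is.null(config$s6k1_ratio))
      1 / (1 + (doses / 100)^0.7) else config$s6k1_ratio
    s6k1_ratio <- s6k1_ratio / s6k1_ratio[1]
    eq <- equivalent_insulin_refit(params, isn_environment(), doses,
                                   s6k1_ratio,
                                   Ie_equiv = if (is.null(config$Ie_equiv)) 10
                                              else config$Ie_equiv)
    links <- link_analysis(params, isn_environment(), eq$Ie_equiv,
                           eq$multipliers, est)
    save_csv(est, "aml_pop_estimates.csv")
    save_csv(links$table, "aml_link_table.csv")
    link_tab <- do.call(rbind, lapply(names(links$links), function(nm) {
      lf <- links$links[[nm]]
      data.frame(link = nm, x = lf$x_name, y = lf$y_name, form = lf$form,
                 A = lf$A, B = lf$B, n = lf$n, residual = lf$residual)
    }))
    save_csv(link_tab, "aml_link_fits.csv")
    list(pop_fit = pfit, equivalent_insulin = eq, links = links,
         link_table = link_tab)
  }
}
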