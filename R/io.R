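#' Read a typed CSV table
#'
#' Validating readers for the small CSV dialects the analyses exchange.
#' The header must match the declared schema exactly and all cells must be
#' numeric (the profile `unit` column excepted); violations raise a schema
#' error naming the offending column before any computation happens.
#'
#' Schemas:
#' * `acf`: `lag_s,G` — one autocorrelation curve; returns [acf_curve()].
#' * `profile`: `distance_um,value,unit` — radial samples with a unit tag
#'   (`per_confocal`, `per_um3`, `nM`, `um2_per_s`); returns
#'   [radial_profile()] (cell radius `a` supplies the r coordinate).
#' * `titration`: `bulk_nM,response`; returns a data.frame.
#' * `simulation`: `time_s,distance_um,L_nM,LR_nM,R_nM` long-format
#'   simulator output; returns a data.frame.
#'
#' @param path CSV file path.
#' @param schema one of `"acf"`, `"profile"`, `"titration"`, `"simulation"`.
#' @param a cell radius in um (profile schema only).
#' @return the typed object for the schema.
#' @export
read_table <- function(path, schema = c("acf", "profile", "titration", "simulation"),
                       a = 10) {
  schema <- match.arg(schema)
  stop_if(!file.exists(path), paste("no such file:", path))
  headers <- list(acf = c("lag_s", "G"),
                  profile = c("distance_um", "value", "unit"),
                  titration = c("bulk_nM", "response"),
                  simulation = c("time_s", "distance_um", "L_nM", "LR_nM", "R_nM"))
  want <- headers[[schema]]
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("schema error: unreadable CSV: ",
                                          conditionMessage(e), call. = FALSE))
  stop_if(nrow(df) == 0, "schema error: file has no data rows")
  if (!identical(names(df), want)) {
    stop("schema error: header must be '", paste(want, collapse = ","),
         "', got '", paste(names(df), collapse = ","), "'", call. = FALSE)
  }
  num_cols <- setdiff(want, "unit")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v) & !is.na(df[[cn]]))
    stop_if(anyNA(v) || length(bad),
            paste0("schema error: non-numeric cell in column '", cn, "'"))
    df[[cn]] <- v
  }
  switch(schema,
         acf = acf_curve(df$lag_s, df$G),
         profile = {
           u <- unique(df$unit)
           stop_if(length(u) != 1, "schema error: mixed units in 'unit' column")
           radial_profile(a + df$distance_um, df$value, unit = u, a = a)
         },
         titration = df,
         simulation = df)
}

#' Write the typed CSV tables
#'
#' Counterparts of [read_table()]; deterministic (no timestamps), so
#' identical inputs give byte-identical files.
#'
#' @param x the object to write ([acf_curve()], [radial_profile()],
#'   titration data.frame, or [rd_sim()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acf_csv <- function(x, path) {
  stopifnot(inherits(x, "acf_curve"))
  utils::write.csv(data.frame(lag_s = x$lag_s, G = x$G), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "radial_profile"))
  utils::write.csv(data.frame(distance_um = x$distance_um, value = x$value,
                              unit = attr(x, "unit")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
write_titration_csv <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("bulk_nM", "response") %in% names(x)))
  utils::write.csv(x[c("bulk_nM", "response")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
write_simulation_csv <- function(x, path) {
  stopifnot(inherits(x, "rd_sim"))
  g <- x$scenario$grid
  long <- data.frame(
    time_s = rep(x$times, each = g$n_cells),
    distance_um = rep(g$centers - g$a, length(x$times)),
    L_nM = as.vector(t(x$L)), LR_nM = as.vector(t(x$LR)), R_nM = as.vector(t(x$R)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a result object to JSON and back
#'
#' `write_result` converts a supported result object to a plain record
#' (numeric content plus a class tag, deterministic field order, full
#' double precision, no timestamps) and writes JSON; `read_result` rebuilds
#' the object, so a write/read round trip is the identity. Plain lists and
#' data.frames pass through unchanged.
#'
#' @param x an [apparent_fit()][apparent_experiment()], [acf_fit][fit_acf()],
#'   [hill_fit][fit_hill()], [fp_solution][fokker_planck_steady()], or any
#'   jsonlite-serializable structure.
#' @param path JSON file path.
#' @return `write_result`: `path` invisibly; `read_result`: the restored
#'   object.
#' @export
write_result <- function(x, path) {
  rec <- as_record(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  stop_if(!file.exists(path), paste("no such file:", path))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_record(rec)
}

as_record <- function(x) UseMethod("as_record")

#' @export
as_record.default <- function(x) x

#' @export
as_record.apparent_fit <- function(x) {
  list(.class = "apparent_fit",
       truth = unclass(x$truth),
       mapping = unclass(x$mapping),
       apparent = unclass(x$apparent),
       closed_form = unclass(x$closed_form),
       residual_norm = x$fit$residual_norm,
       table = x$table)
}

#' @export
as_record.acf_fit <- function(x) {
  list(.class = "acf_fit", converged = x$converged,
       params = if (x$converged) unclass(x$params) else NULL,
       stderr = as.list(x$stderr), residual_norm = x$residual_norm,
       message = x$message)
}

#' @export
as_record.hill_fit <- function(x) {
  list(.class = "hill_fit", converged = x$converged,
       model = if (x$converged) unclass(x$model) else NULL,
       A_max = x$A_max, residual_norm = x$residual_norm, message = x$message)
}

#' @export
as_record.fp_solution <- function(x) {
  list(.class = "fp_solution", model = unclass(x$model),
       K3 = x$K3, K4 = x$K4,
       bc = data.frame(r_um = x$bc[, 1], conc = x$bc[, 2]),
       unit = x$unit, a = x$a)
}

from_record <- function(rec) {
  if (!is.list(rec) || is.null(rec$.class)) return(rec)
  switch(rec$.class,
         apparent_fit = {
           truth <- hill_model(rec$truth$K_d, rec$truth$n)
           mapping <- power_mapping(rec$mapping$A, rec$mapping$b)
           out <- apparent_experiment(rec$table$bulk_nM, mapping, truth)
           out
         },
         fp_solution = {
           m <- diffusivity_model(rec$model$p1, rec$model$p2, rec$model$p3)
           fokker_planck_steady(m, cbind(rec$bc$r_um, rec$bc$conc),
                                unit = rec$unit, a = rec$a)
         },
         rec)
}
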