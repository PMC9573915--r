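#' Extract numeric and character vector assignments from an R data script
#'
#' Restricted, tolerant parser for the `name <- c(...)` data dialect used
#' by supplementary material scripts: only literal `c(...)` assignments
#' are recognized (numbers or quoted strings); anything else is ignored.
#' The script is never executed.
#'
#' @param path path to the script.
#' @return named list of numeric or character vectors.
#' @export
parse_r_data_script <- function(path) {
  if (!file.exists(path)) stop("data script not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # naive comment stripping (data scripts of this dialect do not put '#'
  # inside strings)
  lines <- sub("#.*$", "", lines)
  txt <- paste(lines, collapse = "\n")
  out <- list()
  pat <- "([A-Za-z.][A-Za-z0-9._]*)[[:space:]]*(<-|=)[[:space:]]*c\\("
  pos <- 1L
  repeat {
    m <- regexpr(pat, substr(txt, pos, nchar(txt)), perl = TRUE)
    if (m == -1L) break
    start <- pos + as.integer(m) - 1L
    header <- regmatches(substr(txt, pos, nchar(txt)), m)
    name <- sub(pat, "\\1", header, perl = TRUE)
    open <- start + attr(m, "match.length") - 1L  # position of '('
    depth <- 1L
    i <- open
    while (depth > 0L && i < nchar(txt)) {
      i <- i + 1L
      ch <- substr(txt, i, i)
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
    }
    if (depth != 0L) break  # unbalanced; stop scanning
    body <- substr(txt, open + 1L, i - 1L)
    pos <- i + 1L
    items <- trimws(strsplit(body, ",")[[1L]])
    items <- items[nzchar(items)]
    if (length(items) == 0L) next
    if (all(grepl("^([\"']).*\\1$", items))) {
      out[[name]] <- gsub("^[\"']|[\"']$", "", items)
    } else {
      vals <- suppressWarnings(as.numeric(items))
      if (!any(is.na(vals))) out[[name]] <- vals
      # vectors with expressions/calls inside are skipped, not errors
    }
  }
  out
}

#' Load a bundled case study
#'
#' Reads the Mississippi West Nile virus case study from its
#' supplementary files: the counts and expected counts from the R data
#' script `ms_human_wv_data.R` (parsed, not executed) and the contiguity
#' graph from `mississippi_county.shp`.  If the data script contains a
#' character vector matching the shapefile's region labels, the data are
#' aligned by label; otherwise shapefile record order is assumed.
#'
#' @param name case study name; only `"mississippi"` is bundled
#'   (Pennsylvania and London are external, loaded via
#'   [model_data_from_csv()] + [polygons_to_graph()]).
#' @param supplement_dir directory holding the supplementary files.
#' @param y_var,E_var variable names in the data script holding counts
#'   and expected counts; required if the heuristics find the mapping
#'   ambiguous.
#' @param contiguity_rule passed to [polygons_to_graph()].
#' @param label_field attribute column with county names (default: first
#'   column).
#' @param data_file,shapefile override the default file names.
#' @return a [model_data()].
#' @export
load_case_study <- function(name = c("mississippi"), supplement_dir,
                            y_var = NULL, E_var = NULL,
                            contiguity_rule = "queen", label_field = NULL,
                            data_file = "ms_human_wv_data.R",
                            shapefile = "mississippi_county.shp") {
  name <- match.arg(name)
  script <- file.path(supplement_dir, data_file)
  shp <- file.path(supplement_dir, shapefile)
  dbf <- sub("\\.shp$", ".dbf", shp)
  missing <- c(script, shp, dbf)[!file.exists(c(script, shp, dbf))]
  if (length(missing) > 0L)
    stop("missing case-study file(s): ", paste(missing, collapse = ", "))

  graph <- polygons_to_graph(shp, contiguity_rule, label_field)
  n <- graph$n_regions
  vars <- parse_r_data_script(script)
  num <- vars[vapply(vars, function(v) is.numeric(v) && length(v) == n, logical(1))]
  if (length(num) < 2L)
    stop(sprintf("data script must provide at least two numeric vectors of length %d (found %d)",
                 n, length(num)))
  chr <- vars[vapply(vars, function(v) is.character(v) && length(v) == n, logical(1))]

  # label alignment: a character vector overlapping the shapefile labels
  # fixes the data row order; partial overlap is a hard error
  ord <- seq_len(n)
  for (lv in chr) {
    inter <- length(intersect(lv, graph$region_labels))
    if (inter == 0L) next
    if (!setequal(lv, graph$region_labels))
      stop("region labels in the data script do not match the shapefile; ",
           "unmatched: ",
           paste(union(setdiff(lv, graph$region_labels),
                       setdiff(graph$region_labels, lv)), collapse = ", "))
    ord <- match(graph$region_labels, lv)
    break
  }

  pick <- function(user, patterns, pool) {
    if (!is.null(user)) {
      if (!user %in% names(pool))
        stop("variable '", user, "' not found among length-", n,
             " numeric vectors: ", paste(names(pool), collapse = ", "))
      return(user)
    }
    hit <- names(pool)[grepl(patterns, names(pool), ignore.case = TRUE)]
    if (length(hit) == 1L) hit else character(0)
  }
  ysel <- pick(y_var, "^(y$|obs|case|count|wnv)", num)
  esel <- pick(E_var, "^(e$|exp|offset)", num)
  if (length(ysel) == 0L || length(esel) == 0L || identical(ysel, esel)) {
    # last resort: exactly two vectors, integer-valued one is the count
    if (is.null(y_var) && is.null(E_var) && length(num) == 2L) {
      isint <- vapply(num, function(v) all(v >= 0 & v == round(v)), logical(1))
      if (sum(isint) == 1L) {
        ysel <- names(num)[isint]; esel <- names(num)[!isint]
      }
    }
    if (length(ysel) == 0L || length(esel) == 0L || identical(ysel, esel))
      stop("cannot determine which vectors are the counts (y) and expected ",
           "counts (E); please pass y_var/E_var. Candidates: ",
           paste(names(num), collapse = ", "))
  }
  model_data(num[[ysel]][ord], num[[esel]][ord], graph)
}

#' Write fit reports (JSON + per-region CSV + readable table)
#'
#' @param fit an [fit_mle()] result.
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix (default `"fit"`).
#' @return invisibly, the paths written (`json`, `csv`, `txt`).
#' @export
write_fit_report <- function(fit, out_dir, prefix = "fit") {
  stopifnot(inherits(fit, "icar_fit"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  data <- fit$data
  lambda <- relative_risk(fit$theta_hat, fit$s_hat, data)
  paths <- list(json = file.path(out_dir, paste0(prefix, ".json")),
                csv = file.path(out_dir, paste0(prefix, "_regions.csv")),
                txt = file.path(out_dir, paste0(prefix, "_report.txt")))
  payload <- list(
    theta_hat = list(beta0 = fit$theta_hat$beta0, beta = fit$theta_hat$beta,
                     log_tau = fit$theta_hat$log_tau),
    se_theta = as.list(fit$se_theta),
    estimates = fit$estimates,
    report_scale = fit$report_scale,
    marginal_nll = fit$marginal_nll,
    max_gradient = fit$max_gradient,
    outer_tol = fit$outer_tol,
    converged = fit$converged,
    boundary = fit$boundary,
    n_outer_iterations = fit$n_outer_iterations,
    constraint = unclass(fit$constraint),
    optimizer = fit$optimizer,
    init = as.list(fit$init),
    seed = fit$seed)
  jsonlite::write_json(payload, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(data.frame(
    region_label = data$graph$region_labels,
    y = data$y, E = data$E,
    s_hat = fit$s_hat, cond_sd = fit$s_sd,
    lambda_hat = lambda, fitted = data$E * lambda,
    stringsAsFactors = FALSE), paths$csv, row.names = FALSE)
  txt <- c(
    "Poisson-ICAR fit (Laplace-approximated maximum likelihood)",
    if (!fit$converged) "*** NOT CONVERGED ***",
    if (fit$boundary) "*** spatial dispersion at zero boundary ***",
    sprintf("%-28s %10s %10s", "term", "estimate", "SE"),
    sprintf("%-28s %10.4f %10.4f", fit$estimates$term,
            fit$estimates$estimate, fit$estimates$se),
    sprintf("marginal nll: %.6f", fit$marginal_nll),
    sprintf("max |outer gradient|: %.3e (tolerance %.0e): %s",
            fit$max_gradient, fit$outer_tol,
            if (fit$max_gradient <= fit$outer_tol) "PASS" else "FAIL"),
    sprintf("outer iterations: %d", fit$n_outer_iterations),
    sprintf("seed: %s", ifelse(is.null(fit$seed), "none", fit$seed)))
  writeLines(txt, paths$txt)
  invisible(paths)
}

#' Reload a fit report JSON
#'
#' @param json_path path written by [write_fit_report()].
#' @return list mirroring the JSON payload.
#' @export
read_fit_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
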