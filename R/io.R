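# Report writers tying the analysis stages into reproducible runs: the
# attenuation table for the standard GCR species, Bragg-curve CSV round-trip,
# and field-summary JSON, all with embedded run metadata.

#' Attenuation table for the standard GCR species in aluminum
#'
#' The 5 ions x 4 depths grid of charge-changing interaction fractions
#' (12C, 16O, 24Mg, 28Si, 56Fe at 5/10/20/40 g cm^-2 of aluminum), computed
#' from the geometric cross-section model and rounded to three decimals.
#'
#' @param params A [geometric_params()].
#' @param path Optional CSV output path.
#' @return data.frame (ion label + one column per depth), three-decimal
#'   values.
#' @export
#' @examples
#' run_table1()  # nominal parameters
run_table1 <- function(params = geometric_params(), path = NULL) {
  ions <- list(`12C` = ion_state(6, 12, 600), `16O` = ion_state(8, 16, 600),
               `24Mg` = ion_state(12, 24, 600), `28Si` = ion_state(14, 28, 600),
               `56Fe` = ion_state(26, 56, 600))
  tab <- attenuation_table(ions, c(5, 10, 20, 40),
                           builtin_material("aluminum"), params)
  tab[, -1] <- round(tab[, -1], 3)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

.meta_lines <- function(seed = NULL) {
  c(sprintf("# hzesim %s", as.character(utils::packageVersion("hzesim"))),
    if (!is.null(seed)) sprintf("# seed: %d", seed))
}

#' Write / read a Bragg curve as CSV
#'
#' Columns: depth_g_cm2, ionization_ratio, plus one fluence-fraction column
#' per charge where composition is available. Metadata (package version,
#' seed) is embedded as comment lines.
#'
#' @param curve A `bragg_curve`.
#' @param path CSV path.
#' @param seed Optional seed recorded in the header.
#' @export
write_bragg_csv <- function(curve, path, seed = NULL) {
  stopifnot(inherits(curve, "bragg_curve"))
  df <- data.frame(depth_g_cm2 = curve$depth,
                   ionization_ratio = curve$ionization_ratio)
  if (!is.null(curve$composition)) df <- cbind(df, curve$composition)
  con <- file(path, "w")
  writeLines(.meta_lines(seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(curve)
}

#' @rdname write_bragg_csv
#' @return `read_bragg_csv`: list of class `bragg_curve`.
#' @export
read_bragg_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  comp <- df[, grep("^Z", names(df)), drop = FALSE]
  structure(list(depth = df$depth_g_cm2,
                 ionization_ratio = df$ionization_ratio,
                 composition = if (ncol(comp)) as.matrix(comp) else NULL,
                 step = if (nrow(df) > 1) df$depth_g_cm2[2] - df$depth_g_cm2[1] else NA),
            class = "bragg_curve")
}

#' Write a field summary (or shield study) as JSON
#'
#' @param x A [field_summary()] or `shield_study`.
#' @param path JSON path.
#' @param seed Optional seed recorded in the metadata block.
#' @export
write_field_summary_json <- function(x, path, seed = NULL) {
  meta <- list(package = "hzesim",
               version = as.character(utils::packageVersion("hzesim")),
               seed = seed)
  body <- if (inherits(x, "shield_study")) {
    list(meta = meta, depth_g_cm2 = x$depth,
         before = unclass(x$before), after = unclass(x$after),
         multiplication = x$multiplication, neutron_yield = x$neutron_yield,
         species = x$species)
  } else if (inherits(x, "field_summary")) {
    list(meta = meta, summary = unclass(x))
  } else stop("unsupported object")
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname write_field_summary_json
#' @return `read_field_summary_json`: the parsed list.
#' @export
read_field_summary_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write results in CSV or JSON with run metadata
#'
#' Thin dispatcher used by the analysis drivers: `bragg_curve` objects go to
#' CSV, `field_summary`/`shield_study` objects to JSON, data.frames to CSV.
#' Empty results are an error, never an empty file.
#'
#' @param results Object to write.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param seed Optional seed recorded in the output.
#' @export
run_report <- function(results, path, format = c("csv", "json"), seed = NULL) {
  format <- match.arg(format)
  if (is.null(results) || (is.data.frame(results) && nrow(results) == 0))
    stop("empty results")
  if (inherits(results, "bragg_curve") && format == "csv")
    return(write_bragg_csv(results, path, seed))
  if (inherits(results, c("field_summary", "shield_study")) && format == "json")
    return(write_field_summary_json(results, path, seed))
  if (is.data.frame(results) && format == "csv") {
    con <- file(path, "w")
    writeLines(.meta_lines(seed), con)
    utils::write.csv(results, con, row.names = FALSE)
    close(con)
    return(invisible(results))
  }
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }
  stop("unknown format for this object")
}
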