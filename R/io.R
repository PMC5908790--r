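# File formats: UTF-8 comma-separated CSV with a header row and "." decimal;
# concentrations in nM throughout; in-vivo days are 0-based from randomization.

#' Read a long-format plate CSV
#'
#' @param path CSV with columns `line_id`, `agent`, `conc_nM`, `replicate`,
#'   `signal`, `well_role` (plus optional `tumor_type`, `conc_A_nM`,
#'   `conc_B_nM` for mixtures).
#' @return Data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "agent", "conc_nM", "signal", "well_role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a MAF-like mutation CSV
#'
#' @param path CSV with columns `line_id`, `gene`, `protein_change`.
#' @return Data.frame.
#' @export
read_maf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("line_id", "gene", "protein_change"), names(df))
  if (length(miss)) stop("mutation file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a table as CSV
#'
#' @param df Data.frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the package
#' version, the seed, the configuration, MD5 checksums of the input files and
#' any aggregated warnings.
#'
#' @param path Output YAML path.
#' @param config A configuration object (list-like).
#' @param seed The seed used.
#' @param inputs Character vector of input file paths to checksum.
#' @param warnings Character vector of aggregated warnings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NA_integer_,
                           inputs = character(), warnings = character()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(
    package = "panelscreen",
    version = as.character(utils::packageVersion("panelscreen")),
    seed = seed,
    config = .config_as_list(config),
    input_md5 = sums,
    warnings = as.list(warnings)), path)
  invisible(path)
}

.config_as_list <- function(config) {
  if (is.null(config)) return(list())
  out <- unclass(config)
  lapply(out, function(x) if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
}

#' Write a configuration object as YAML
#'
#' @param config A [panel_config()], [combo_config()] or [xeno_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}
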