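# File formats: the per-compound spectral table ("molecule" CSV dialect),
# 2-column spectrum CSVs, and YAML/JSON run configurations.
#
# Molecule-table dialect: comma separator, dot decimal, header row, columns
# wavelength [nm], incident spectral photon flux density [Einstein cm^-2
# s^-1 nm^-1], molar absorption coefficient [L mol^-1 cm^-1], photolysis
# quantum yield, water absorbance [cm^-1]. The phi and Aw columns may be
# disabled by filling the whole column with the sentinel -1 (quantum yield
# then comes from the scalar reactivity input; absorbance from the
# DOC-based estimate). Mixed -1/values in a column are an error: the
# sentinel has whole-column semantics.

.DEFAULT_HEADER_MAP <- c(wavelength = "wl", p0sun = "p0sun", epsilon = "EP",
                         phi = "phi", aw = "Aw")

.column_state <- function(v, what) {
  if (all(v == -1)) return("disabled")
  if (any(v == -1))
    stop(sprintf("mixed -1/values in the %s column: the sentinel applies to whole columns", what))
  "enabled"
}

#' Read a per-compound spectral table
#'
#' Parses the molecule CSV dialect and resolves the column-priority rules:
#' an enabled `Aw` column is used with priority as the water absorbance
#' (otherwise the DOC-based estimate applies downstream); an enabled `phi`
#' column is used with priority over the scalar quantum yield.
#'
#' @param path CSV file path.
#' @param header_map named character vector mapping the canonical names
#'   `wavelength`, `p0sun`, `epsilon`, `phi`, `aw` to the file's headers;
#'   default `c(wavelength = "wl", p0sun = "p0sun", epsilon = "EP",
#'   phi = "phi", aw = "Aw")`.
#' @return list with spectra `p0`, `epsilon`, and `phi`, `aw` (spectra or
#'   NULL when their columns are disabled), plus a `report` describing
#'   which sources were resolved.
#' @export
read_molecule_csv <- function(path, header_map = .DEFAULT_HEADER_MAP) {
  if (!all(names(.DEFAULT_HEADER_MAP) %in% names(header_map)))
    stop("header_map must name wavelength, p0sun, epsilon, phi, aw")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(header_map), names(df))
  if (length(missing))
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing, collapse = ", ")))
  wl <- df[[header_map[["wavelength"]]]]
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  ep <- df[[header_map[["epsilon"]]]]
  if (any(ep < 0)) stop("negative molar absorption coefficient")
  phi_col <- df[[header_map[["phi"]]]]
  aw_col <- df[[header_map[["aw"]]]]
  phi_state <- .column_state(phi_col, "phi")
  aw_state <- .column_state(aw_col, "Aw")
  out <- list(
    p0 = spectrum(wl, df[[header_map[["p0sun"]]]], "photon_flux_density"),
    epsilon = spectrum(wl, ep, "molar_absorption"),
    phi = if (phi_state == "enabled")
      spectrum(wl, phi_col, "photon_flux_density") else NULL,
    aw = if (aw_state == "enabled")
      spectrum(wl, aw_col, "absorbance_per_cm") else NULL,
    report = list(
      absorbance_source = if (aw_state == "enabled") "Aw column"
      else "DOC-based estimate",
      phi_source = if (phi_state == "enabled") "phi column"
      else "scalar quantum yield")
  )
  # the phi column holds dimensionless yields; re-tag the container
  if (!is.null(out$phi)) out$phi$kind <- "photon_flux_density"
  out
}

#' Write a per-compound spectral table
#'
#' Inverse of [read_molecule_csv()]: disabled `phi`/`aw` columns are
#' written as whole-column -1 sentinels. Round-trips losslessly.
#'
#' @param molecule list with `p0`, `epsilon` and optional `phi`, `aw`
#'   spectra sharing the `p0` grid.
#' @param path output CSV path.
#' @param header_map as in [read_molecule_csv()].
#' @return `path`, invisibly.
#' @export
write_molecule_csv <- function(molecule, path,
                               header_map = .DEFAULT_HEADER_MAP) {
  wl <- molecule$p0$wavelength
  df <- data.frame(wl, molecule$p0$value, spectrum_at(molecule$epsilon, wl),
                   if (!is.null(molecule$phi)) spectrum_at(molecule$phi, wl)
                   else rep(-1, length(wl)),
                   if (!is.null(molecule$aw)) spectrum_at(molecule$aw, wl)
                   else rep(-1, length(wl)))
  names(df) <- unname(header_map[c("wavelength", "p0sun", "epsilon",
                                   "phi", "aw")])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a 2-column spectrum CSV
#'
#' @param path CSV with columns `wavelength`, `value`.
#' @param kind the spectrum kind tag (see [spectrum()]).
#' @return a [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = "photon_flux_density") {
  df <- utils::read.csv(path)
  spectrum(df[[1]], df[[2]], kind)
}

#' @rdname read_spectrum_csv
#' @param sp a [spectrum()] to write.
#' @export
write_spectrum_csv <- function(sp, path) {
  utils::write.csv(data.frame(wavelength = sp$wavelength, value = sp$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

.water_from_config <- function(cfg) {
  g <- function(nm, default = 0) {
    v <- cfg[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  doc <- if (!is.null(cfg$NPOC)) as.numeric(cfg$NPOC) else g("DOC")
  hco3 <- g("CHCO3")
  co3 <- g("CCO3")
  if (!is.null(cfg$Alk) && !is.null(cfg$pH)) {
    sp <- carbonate_from_alkalinity(as.numeric(cfg$Alk), as.numeric(cfg$pH))
    hco3 <- sp[["bicarbonate"]]
    co3 <- sp[["carbonate"]]
  }
  water_body(g("d", 1), nitrate = g("CNO3"), nitrite = g("CNO2"),
             bicarbonate = hco3, carbonate = co3, doc = doc,
             bromide = g("CBr"), psi = g("psi", 1))
}

.reactivity_from_config <- function(cfg) {
  g <- function(nm, default = 0) {
    v <- cfg[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  y <- c(phot = g("y_Phot"), oh = g("y_OH"), co3 = g("y_CO3"),
         o2 = g("y_1O2"), dom = g("y_3DOM"))
  photo_reactivity(phi_direct = g("fi_P"), k_oh = g("kP_OH"),
                   k_co3 = g("kP_CO3"), k_1o2 = g("kP_1O2"),
                   k_3cdom = g("kP_3DOM"),
                   doc_half = g("DOC_half", Inf), yields = y)
}

#' Load a run configuration file
#'
#' YAML (or JSON, which YAML subsumes) with blocks `water` (fields `d`,
#' `CNO3`, `CNO2`, `CHCO3`, `CCO3`, `DOC`/`NPOC`, `CBr`, `psi`, or `Alk` +
#' `pH`), `reactivity` (`fi_P`, `kP_OH`, `kP_CO3`, `kP_1O2`, `kP_3DOM`,
#' `DOC_half`, `y_*`), `molecule` (`file`: a molecule CSV path, resolved
#' relative to the config file), and optional `sweep`
#' (`x_var`/`x_grid`/`y_var`/`y_grid`, or -1/-2 sentinels inside the other
#' blocks).
#'
#' @param path config file path.
#' @return list with `water`, `reactivity`, `molecule`, `sweep` (or NULL)
#'   and the raw config.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$water)) stop("config lacks a 'water' block")
  if (is.null(cfg$molecule$file)) stop("config lacks molecule: file")
  mol_path <- cfg$molecule$file
  if (!file.exists(mol_path))
    mol_path <- file.path(dirname(path), cfg$molecule$file)
  if (!file.exists(mol_path))
    stop(sprintf("molecule file not found: %s", cfg$molecule$file))
  # legacy sentinel support inside the water/reactivity blocks
  merged <- c(cfg$water, cfg$reactivity)
  sent <- resolve_sweep_sentinels(merged)
  water_cfg <- cfg$water
  react_cfg <- cfg$reactivity
  for (v in c(sent$x_var, sent$y_var)) {
    water_cfg[[v]] <- NULL
    react_cfg[[v]] <- NULL
  }
  sweep <- cfg$sweep
  if (!is.null(sent$x_var)) {
    sweep$x_var <- sent$x_var
    if (!is.null(sent$y_var)) sweep$y_var <- sent$y_var
  }
  list(water = .water_from_config(water_cfg),
       reactivity = .reactivity_from_config(react_cfg),
       molecule = read_molecule_csv(mol_path),
       sweep = sweep, raw = cfg)
}
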