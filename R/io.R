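# Parameter-file round-trips, the packaged reference fixture, and result
# serialization. The parameter format is flat key = value text with explicit
# unit suffixes in the key names, which round-trips bit-exactly and diffs
# cleanly.

parameter_schema <- function() {
  keys <- c(
    temperature_K = "temperature",
    "perm.am.Na_m_s" = "perm.am.Na",
    "perm.lm.K_m_s" = "perm.lm.K", "perm.lm.Cl_m_s" = "perm.lm.Cl",
    "perm.sm.K_m_s" = "perm.sm.K", "perm.sm.Cl_m_s" = "perm.sm.Cl",
    "perm.tj.Na_m_s" = "perm.tj.Na", "perm.tj.K_m_s" = "perm.tj.K",
    "perm.tj.Cl_m_s" = "perm.tj.Cl", "perm.tj.Gluc_m_s" = "perm.tj.Gluc",
    "perm.ibm.Na_m_s" = "perm.ibm.Na", "perm.ibm.K_m_s" = "perm.ibm.K",
    "perm.ibm.Cl_m_s" = "perm.ibm.Cl", "perm.ibm.Gluc_m_s" = "perm.ibm.Gluc",
    "lp.am_m_s_Pa" = "lp.am", "lp.lm_m_s_Pa" = "lp.lm",
    "lp.sm_m_s_Pa" = "lp.sm", "lp.tj_m_s_Pa" = "lp.tj",
    "lp.ibm_m_s_Pa" = "lp.ibm",
    "sigma.tj.Na" = "sigma.tj.Na", "sigma.tj.K" = "sigma.tj.K",
    "sigma.tj.Cl" = "sigma.tj.Cl", "sigma.tj.Gluc" = "sigma.tj.Gluc",
    "sigma.ibm.Na" = "sigma.ibm.Na", "sigma.ibm.K" = "sigma.ibm.K",
    "sigma.ibm.Cl" = "sigma.ibm.Cl", "sigma.ibm.Gluc" = "sigma.ibm.Gluc",
    "pump.Ppump_mol_s_V_m2" = "pump.Ppump", "pump.Epump_V" = "pump.Epump",
    "pump.KNa_mM" = "pump.KNa", "pump.KK_mM" = "pump.KK",
    "sglt1.Pmax_m_s" = "sglt1.Pmax", "sglt1.Km_mM" = "sglt1.Km",
    "sglt1.nW" = "sglt1.nW",
    "glut1.Jmax_mol_m2_s" = "glut1.Jmax", "glut1.K_mM" = "glut1.K",
    "glut1.fLm" = "glut1.fLm",
    "nak2cl.kAm_mol_m2_s_mM4" = "nak2cl.kAm",
    "nak2cl.kSm_mol_m2_s_mM4" = "nak2cl.kSm",
    "geometry.muAm_per_Pa" = "geometry.muAm",
    "geometry.muLm_per_Pa" = "geometry.muLm",
    "geometry.muSm_per_Pa" = "geometry.muSm",
    "geometry.volLisRef_m3_m2" = "geometry.volLisRef",
    "geometry.DcMA_mol_m2" = "geometry.DcMA",
    "geometry.zA" = "geometry.zA",
    "geometry.volCRef_m3_m2" = "geometry.volCRef")
  keys
}

#' Load a model parameter file
#'
#' Reads the flat `key = value` format written by [save_parameters()]
#' (explicit unit suffixes in the key names, `#` comments). Unknown keys and
#' invariant violations (e.g. a reflection coefficient outside `[0, 1]`) are
#' rejected with an error naming the key.
#'
#' @param path Path to the parameter file.
#' @return A validated [model_parameters()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  schema <- parameter_schema()
  unknown <- setdiff(keys, names(schema))
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  missing <- setdiff(names(schema), keys)
  if (length(missing)) stop("missing parameter key(s): ",
                            paste(missing, collapse = ", "))

  get <- function(key) vals[match(key, keys)]
  p <- structure(list(
    temperature = get("temperature_K"),
    constants = physical_constants(get("temperature_K")),
    perm = list(
      am = list(Na = get("perm.am.Na_m_s")),
      lm = list(K = get("perm.lm.K_m_s"), Cl = get("perm.lm.Cl_m_s")),
      sm = list(K = get("perm.sm.K_m_s"), Cl = get("perm.sm.Cl_m_s")),
      tj = list(Na = get("perm.tj.Na_m_s"), K = get("perm.tj.K_m_s"),
                Cl = get("perm.tj.Cl_m_s"), Gluc = get("perm.tj.Gluc_m_s")),
      ibm = list(Na = get("perm.ibm.Na_m_s"), K = get("perm.ibm.K_m_s"),
                 Cl = get("perm.ibm.Cl_m_s"), Gluc = get("perm.ibm.Gluc_m_s"))),
    lp = list(am = get("lp.am_m_s_Pa"), lm = get("lp.lm_m_s_Pa"),
              sm = get("lp.sm_m_s_Pa"), tj = get("lp.tj_m_s_Pa"),
              ibm = get("lp.ibm_m_s_Pa")),
    sigma = list(
      tj = c(Na = get("sigma.tj.Na"), K = get("sigma.tj.K"),
             Cl = get("sigma.tj.Cl"), Gluc = get("sigma.tj.Gluc")),
      ibm = c(Na = get("sigma.ibm.Na"), K = get("sigma.ibm.K"),
              Cl = get("sigma.ibm.Cl"), Gluc = get("sigma.ibm.Gluc"))),
    pump = pump_parameters(Ppump = get("pump.Ppump_mol_s_V_m2"),
                           Epump = get("pump.Epump_V"),
                           KNa = get("pump.KNa_mM"), KK = get("pump.KK_mM")),
    sglt1 = sglt1_parameters(Pmax = get("sglt1.Pmax_m_s"),
                             Km = get("sglt1.Km_mM"), nW = get("sglt1.nW")),
    glut1 = list(Jmax = get("glut1.Jmax_mol_m2_s"), K = get("glut1.K_mM"),
                 fLm = get("glut1.fLm")),
    nak2cl = list(kAm = get("nak2cl.kAm_mol_m2_s_mM4"),
                  kSm = get("nak2cl.kSm_mol_m2_s_mM4")),
    geometry = list(muAm = get("geometry.muAm_per_Pa"),
                    muLm = get("geometry.muLm_per_Pa"),
                    muSm = get("geometry.muSm_per_Pa"),
                    volLisRef = get("geometry.volLisRef_m3_m2"),
                    DcMA = get("geometry.DcMA_mol_m2"),
                    zA = get("geometry.zA"),
                    volCRef = get("geometry.volCRef_m3_m2"))
  ), class = "model_parameters")
  tryCatch(validate_parameters(p), error = function(e)
    stop("invalid parameter file ", path, ": ", conditionMessage(e)))
  p
}

#' Save a model parameter file
#'
#' Writes the flat key-value format read by [load_parameters()]; a
#' save -> load -> save round-trip is byte-identical.
#'
#' @param params A [model_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  schema <- parameter_schema()
  vals <- vapply(unname(schema), function(p) param_get(params, p), numeric(1))
  lines <- c("# proxtub model parameters (MKSA; concentrations in mM = mol/m^3)",
             sprintf("%s = %.17g", names(schema), vals))
  writeLines(lines, path)
  invisible(path)
}

#' The calibrated reference parameter fixture
#'
#' Parameters calibrated so the solved model reproduces the reference
#' operating point of the S3-segment epithelium: at 1 mM bilateral glucose a
#' pump flux of ~541 pmol cm^-2 s^-1, a cell potential near -78.5 mV, a lis
#' barely above bath osmolarity at ~1.0007 atm driving ~4.9 nL cm^-2 s^-1
#' across the interspace basement membrane; at 6 mM glucose a hyperosmotic
#' absorbate (~345 mosM vs 306 mosM baths) without recirculation. The
#' calibration residuals are documented in the fixture file comments.
#'
#' @return A [model_parameters()] object.
#' @export
reference_parameters <- function() {
  load_parameters(system.file("extdata", "reference_parameters.txt",
                              package = "proxtub", mustWork = TRUE))
}

#' Write protocol results to a directory
#'
#' One CSV per result table (RFC-4180, header row, numbers at 10 significant
#' digits for byte-stable regression comparisons) plus a JSON metadata file
#' holding the protocol name, package version and column names. Deterministic
#' column order; steady-state protocols re-run under an identical
#' configuration reproduce the files byte-identically.
#'
#' @param result A `protocol_result` or `transient_history`.
#' @param dir Output directory (created if needed).
#' @param name Base file name; defaults to the protocol name.
#' @return Named character vector of the files written.
#' @export
write_results <- function(result, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(result, "transient_history")) {
    tab <- result$table
    if (is.null(name)) name <- "transient"
    protocol <- "transient"
  } else if (inherits(result, "protocol_result")) {
    tab <- result$table
    if (is.null(name)) name <- result$protocol
    protocol <- result$protocol
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))

  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 10))
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)

  meta <- list(protocol = protocol,
               package = "proxtub",
               version = as.character(utils::packageVersion("proxtub")),
               columns = names(tab), rows = nrow(tab))
  metafile <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, metafile, auto_unbox = TRUE, pretty = TRUE)
  c(table = csv, meta = metafile)
}
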