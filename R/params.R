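# Parameter vocabulary -------------------------------------------------------

.deb_temp_keys <- c("T_ref", "T_A", "T_L", "T_AL", "T_H", "T_AH")

.deb_core_keys <- c("z", "F_m", "p_Am", "kap_X", "kap_P", "v", "kap", "kap_R",
                    "p_M", "p_T", "k_J", "E_G",
                    "E_Hb", "E_Hr", "E_Hs", "E_Hj", "E_Hp",
                    "h_a", "s_g", "del_Mb", "del_M", "K_X", "s_M")

.deb_aux_keys <- c("d_V", "d_E", "mu_E", "w_E", "w_V", "dw_ww_ratio")

.deb_all_keys <- c(.deb_temp_keys, .deb_core_keys, .deb_aux_keys)

# keys that must be present in any parameter set
.deb_required_keys <- c(.deb_temp_keys,
                        c("z", "p_Am", "kap_X", "kap_P", "v", "kap", "kap_R",
                          "p_M", "p_T", "k_J", "E_G", "del_M", "K_X"),
                        .deb_aux_keys)

# additional keys required for the full 'asj' life cycle
.deb_asj_keys <- c("E_Hb", "E_Hs", "E_Hj", "E_Hp", "h_a", "s_g", "del_Mb")

#' Construct and validate a DEB parameter set
#'
#' A `deb_params` object holds the full species-specific parameter set of the
#' 'asj' Dynamic Energy Budget model: core energetics (assimilation,
#' conductance, allocation, maintenance, costs of structure), maturity
#' thresholds that delimit life stages (birth, larval release, settlement,
#' end of metamorphosis, puberty), Weibull--Gompertz ageing, shape
#' coefficients before and after metamorphosis, the five-parameter Arrhenius
#' temperature block, the Holling half-saturation constant `K_X`, and
#' auxiliary composition parameters used to convert state to weights.
#'
#' `{p_Am}` and `v` are stored at their pre-acceleration reference; during and
#' after metabolic acceleration both are multiplied by the acceleration
#' factor (see [acceleration_factor()]).  Parameter sets without maturity
#' thresholds (e.g. the standard-model Pacific oyster set) are supported in
#' `"std"` mode, restricted to post-metamorphic simulations.
#'
#' @param x named list or named numeric vector of parameter values using the
#'   canonical symbol vocabulary (`T_ref`, `T_A`, `T_L`, `T_AL`, `T_H`,
#'   `T_AH`, `z`, `F_m`, `p_Am`, `kap_X`, `kap_P`, `v`, `kap`, `kap_R`,
#'   `p_M`, `p_T`, `k_J`, `E_G`, `E_Hb`, `E_Hr`, `E_Hs`, `E_Hj`, `E_Hp`,
#'   `h_a`, `s_g`, `del_Mb`, `del_M`, `K_X`, `s_M`, plus the auxiliary block
#'   `d_V`, `d_E`, `mu_E`, `w_E`, `w_V`, `dw_ww_ratio`).
#' @param species optional species label carried along in outputs.
#'
#' @return object of class `deb_params`: a named list of numeric parameters
#'   with attributes `species` and `mode` (`"asj"` or `"std"`).
#' @seealso [deb_species()], [read_deb_params()], [compound_parameters()]
#' @export
#' @examples
#' p <- deb_species("o_edulis")
#' p$kap      # allocation fraction to soma
#' p$p_Am     # maximum surface-specific assimilation rate, J/d/cm^2
deb_params <- function(x, species = NULL) {
  if (is.numeric(x)) x <- as.list(x)
  stopifnot(is.list(x))
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) {
    stop("all parameters must be named")
  }
  unknown <- setdiff(nm, .deb_all_keys)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(.deb_all_keys, collapse = ", "))
  }
  missing <- setdiff(.deb_required_keys, nm)
  if (length(missing)) {
    stop("missing required parameter key(s): ",
         paste(missing, collapse = ", "))
  }
  p <- lapply(x, function(v) as.numeric(v)[1])
  mode <- if (all(.deb_asj_keys %in% nm)) "asj" else "std"
  obj <- structure(p, class = "deb_params",
                   species = if (is.null(species)) NA_character_ else species,
                   mode = mode)
  validate_deb_params(obj)
  obj
}

#' @rdname deb_params
#' @param params a `deb_params` object.
#' @export
validate_deb_params <- function(params) {
  p <- params
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid parameters: ", msg)
  pos <- c("T_ref", "T_A", "T_L", "T_AL", "T_H", "T_AH", "p_Am", "v", "p_M",
           "k_J", "E_G", "K_X", "d_V", "d_E", "mu_E", "w_E", "w_V")
  for (k in pos) chk(p[[k]] > 0, paste(k, "must be strictly positive"))
  chk(p$p_T >= 0, "p_T must be non-negative")
  chk(p$kap > 0 && p$kap < 1, "kap must lie in (0,1)")
  chk(p$kap_X > 0 && p$kap_X <= 1, "kap_X must lie in (0,1]")
  chk(p$kap_P >= 0 && p$kap_P < 1, "kap_P must lie in [0,1)")
  chk(p$kap_X + p$kap_P <= 1, "kap_X + kap_P cannot exceed 1")
  chk(p$kap_R >= 0 && p$kap_R <= 1, "kap_R must lie in [0,1]")
  chk(p$del_M > 0 && p$del_M < 1, "del_M must lie in (0,1)")
  chk(p$dw_ww_ratio > 0 && p$dw_ww_ratio < 1, "dw_ww_ratio must lie in (0,1)")
  chk(p$T_L < p$T_ref && p$T_ref < p$T_H,
      "temperature tolerance range must satisfy T_L < T_ref < T_H")
  if (!is.null(p$s_M)) chk(p$s_M >= 1, "s_M must be >= 1")
  if (attr(params, "mode") == "asj") {
    chk(p$del_Mb > 0 && p$del_Mb < 1, "del_Mb must lie in (0,1)")
    thr <- c(p$E_Hb, p$E_Hr, p$E_Hs, p$E_Hj, p$E_Hp)
    thr <- thr[!vapply(thr, is.null, logical(1))]
    thr <- unlist(thr)
    chk(all(thr > 0), "maturity thresholds must be strictly positive")
    chk(all(diff(thr) >= 0),
        "maturity thresholds must be ordered E_Hb <= E_Hr <= E_Hs <= E_Hj <= E_Hp")
    chk(p$h_a > 0, "h_a must be strictly positive")
    chk(p$s_g >= 0, "s_g must be non-negative")
  }
  invisible(params)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("DEB parameter set (", attr(x, "mode"), " model)",
      if (!is.na(attr(x, "species"))) paste0(" - ", attr(x, "species")), "\n",
      sep = "")
  keys <- intersect(.deb_all_keys, names(x))
  vals <- vapply(keys, function(k) x[[k]], numeric(1))
  print(data.frame(value = signif(vals, 6), row.names = keys))
  invisible(x)
}

#' Load a packaged species parameter set
#'
#' Three parameter sets ship with the package: `"o_edulis"` (European flat
#' oyster, full 'asj' set), `"c_gigas_amp"` (Pacific oyster, Add-my-Pet style
#' 'asj' set) and `"c_gigas_std"` (Pacific oyster, standard-model set without
#' maturity thresholds, usable for post-metamorphic simulation only).
#'
#' @param species one of `"o_edulis"`, `"c_gigas_amp"`, `"c_gigas_std"`.
#' @return a [deb_params] object.
#' @export
deb_species <- function(species = c("o_edulis", "c_gigas_amp", "c_gigas_std")) {
  species <- match.arg(species)
  path <- system.file("extdata", "params", paste0(species, ".csv"),
                      package = "oysterDEB", mustWork = TRUE)
  read_deb_params(path, species = species)
}

#' Read and write DEB parameter files
#'
#' Parameter files are flat two-column CSV tables (`key,value`) using the
#' canonical parameter vocabulary.  `write_deb_params()` followed by
#' `read_deb_params()` is the identity.
#'
#' @param path file path.
#' @param species optional species label attached to the returned object.
#' @return `read_deb_params()` returns a [deb_params] object;
#'   `write_deb_params()` returns `path` invisibly.
#' @export
read_deb_params <- function(path, species = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(tab))) {
    stop("parameter file must have columns 'key' and 'value': ", path)
  }
  if (anyDuplicated(tab$key)) {
    stop("duplicated parameter key(s) in ", path)
  }
  x <- as.list(as.numeric(tab$value))
  names(x) <- tab$key
  deb_params(x, species = species)
}

#' @rdname read_deb_params
#' @param params a `deb_params` object.
#' @export
write_deb_params <- function(params, path) {
  stopifnot(inherits(params, "deb_params"))
  keys <- intersect(.deb_all_keys, names(params))
  vals <- vapply(keys, function(k) format(params[[k]], digits = 15), character(1))
  utils::write.csv(data.frame(key = keys, value = vals),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Compound parameters --------------------------------------------------------

#' Derived (compound) DEB parameters
#'
#' Computes the standard compound quantities implied by a primary parameter
#' set: maximum reserve capacity `E_m = {p_Am}/v` (J cm^-3), maximum
#' structural length `L_m = kap*{p_Am}/[p_M]` (cm), the zoom factor
#' `z = L_m / 1 cm`, the energy investment ratio `g = E_G/(kap*E_m)`, the
#' somatic maintenance rate coefficient `k_M = [p_M]/E_G` (1/d), the
#' acceleration factor `s_M`, the ultimate structural and physical lengths at
#' scaled food level `f`, the von Bertalanffy rate `r_B` at `f`, and the
#' reserve residence time `t_E = L/v` at a reference structural length.
#'
#' `E_m`, `g` and `t_E`-per-unit-`L` are invariant under metabolic
#' acceleration because `{p_Am}` and `v` are accelerated by the same factor.
#' `s_M` is taken from the parameter set when present; use
#' [acceleration_factor()] to obtain the value emerging from the life-cycle
#' solution.
#'
#' @param params a [deb_params] object.
#' @param f scaled functional response used for the ultimate-size entries.
#' @param L_ref structural length (cm) at which the reserve residence time is
#'   reported.
#' @return named list of derived quantities.
#' @export
#' @examples
#' cp <- compound_parameters(deb_species("o_edulis"))
#' cp$E_m   # 91 / 0.020 = 4550 J cm^-3
compound_parameters <- function(params, f = 1, L_ref = 1) {
  p <- params
  E_m <- p$p_Am / p$v
  L_m <- p$kap * p$p_Am / p$p_M
  s_M <- if (!is.null(p$s_M)) p$s_M else 1
  g <- p$E_G / (p$kap * E_m)
  k_M <- p$p_M / p$E_G
  L_inf <- s_M * f * L_m                  # structural, cm
  Lw_inf <- L_inf / p$del_M               # physical, cm
  # von Bertalanffy growth rate at constant f (post-metamorphic, T = T_ref)
  r_B <- k_M / 3 / (1 + f / g)
  list(E_m = E_m, L_m = L_m, z = L_m / 1, g = g, k_M = k_M, s_M = s_M,
       L_inf = L_inf, Lw_inf = Lw_inf, r_B = r_B,
       t_E = L_ref / p$v,
       E_0 = NA_real_)
}
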