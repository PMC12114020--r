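.qmmmion_env <- new.env(parent = emptyenv())

#' Engine parameter table
#'
#' Loads the per-element parameter table used by the fluctuating-charge
#' surrogate engine and the classical terms: electronegativity `chi`
#' (hartree/e), hardness `eta` (hartree/e^2), Bondi van der Waals radius
#' (angstrom), default MM point charge (e) and Lennard-Jones parameters
#' (hartree, angstrom). The shipped defaults make nitrogen the softest
#' element so that holes localize on the nitrogen-rich nucleobase.
#'
#' @param path optional path to a YAML parameter file with the same layout
#'   as the shipped `eem_params.yaml`; `NULL` loads the package default.
#' @return a list with elements `elements` (data.frame keyed by element
#'   symbol) and `water` (TIP3P-like O/H point charges).
#' @export
load_engine_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.qmmmion_env$params)) return(.qmmmion_env$params)
    path <- system.file("extdata", "eem_params.yaml", package = "qmmmion",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- yaml::read_yaml(path)
  el <- do.call(rbind, lapply(names(raw$elements), function(sym) {
    p <- raw$elements[[sym]]
    data.frame(element = sym, chi = p$chi, eta = p$eta,
               vdw_radius = p$vdw_radius, mm_charge = p$mm_charge,
               lj_eps = p$lj_eps, lj_sigma = p$lj_sigma,
               stringsAsFactors = FALSE)
  }))
  rownames(el) <- el$element
  params <- list(elements = el, water = raw$water)
  if (cache) .qmmmion_env$params <- params
  params
}

# Per-atom parameter lookup; waters get TIP3P point charges.
element_params <- function(element, component = NULL, params = NULL) {
  if (is.null(params)) params <- load_engine_params()
  el <- params$elements
  unknown <- setdiff(unique(element), rownames(el))
  if (length(unknown))
    stop("no engine parameters for element(s): ", paste(unknown, collapse = ", "))
  out <- el[element, c("chi", "eta", "vdw_radius", "mm_charge",
                       "lj_eps", "lj_sigma")]
  rownames(out) <- NULL
  if (!is.null(component)) {
    w <- component == "WATER"
    out$mm_charge[w & element == "O"] <- params$water$o_charge
    out$mm_charge[w & element == "H"] <- params$water$h_charge
  }
  out
}
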