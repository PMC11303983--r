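#' @keywords internal
.param_fields <- c("g_max", "k_P", "H_S", "H_O", "y_P", "p_O", "p_S", "m",
                   "alpha_P", "O_b", "S_b", "P_b", "c")

.state_fields <- c("N_CB", "N_SB", "O", "S", "P")

#' Model parameter set
#'
#' Constructs and validates the rate constants and background concentrations
#' of the mutual-inhibition ecosystem model.  Parameter sets are immutable
#' value objects: asymmetric configurations are derived with
#' [update_parameters()], never by mutating an existing set.
#'
#' @param g_max Maximum specific growth rate, 1/h (shared by both groups).
#' @param k_P Half-saturation constant on phosphorus, uM (shared).
#' @param H_S Half-inhibition constant of sulfide on cyanobacteria, uM.
#' @param H_O Half-inhibition constant of oxygen on sulfur-reducing
#'   bacteria, uM.
#' @param y_P Yield on phosphorus, cells/uM (shared).
#' @param p_O Oxygen production constant of cyanobacteria, uM/cell.
#' @param p_S Sulfide production constant of sulfur-reducing bacteria,
#'   uM/cell.
#' @param m Mortality rate, 1/h (shared).
#' @param alpha_P Phosphorus diffusivity, 1/h.
#' @param O_b Background oxygen concentration, uM.
#' @param S_b Background sulfide concentration, uM.
#' @param P_b Background phosphorus concentration, uM.
#' @param c Oxidation rate coefficient of the O*S reaction, 1/(uM h).
#'
#' @return An object of class `symtip_params`: a named list of the thirteen
#'   parameters.
#' @seealso [symmetric_parameters()] for the reference symmetric
#'   configuration.
#' @export
model_parameters <- function(g_max, k_P, H_S, H_O, y_P, p_O, p_S, m,
                             alpha_P, O_b, S_b, P_b, c) {
  p <- list(g_max = g_max, k_P = k_P, H_S = H_S, H_O = H_O, y_P = y_P,
            p_O = p_O, p_S = p_S, m = m, alpha_P = alpha_P,
            O_b = O_b, S_b = S_b, P_b = P_b, c = c)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  }
  for (nm in c("g_max", "m", "y_P", "k_P", "H_S", "H_O"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  structure(p, class = "symtip_params")
}

#' Symmetric reference parameterization
#'
#' The parameter set under which the two functional groups are exact mirror
#' images of each other: shared growth, yield and mortality constants,
#' equal half-inhibition constants (`H_S == H_O`), equal substrate
#' production constants (`p_O == p_S`) and equal background substrate
#' concentrations.
#'
#' @return A `symtip_params` object.
#' @export
#' @examples
#' p <- symmetric_parameters()
#' is_system_symmetric(p)
symmetric_parameters <- function() {
  model_parameters(
    g_max = 0.1,      # 1/h
    k_P   = 0.5,      # uM
    H_S   = 100,      # uM
    H_O   = 100,      # uM
    y_P   = 1.67e8,   # cells/uM
    p_O   = 3.00e-8,  # uM/cell
    p_S   = 3.00e-8,  # uM/cell
    m     = 0.04,     # 1/h
    alpha_P = 0.1,    # 1/h
    O_b   = 100,      # uM
    S_b   = 100,      # uM
    P_b   = 10,       # uM
    c     = 0.1       # 1/(uM h)
  )
}

#' Copy a parameter set with overrides
#'
#' @param params A `symtip_params` object.
#' @param ... Named parameter values replacing those in `params`.
#' @return A new, validated `symtip_params` object; `params` is unchanged.
#' @export
#' @examples
#' asym <- update_parameters(symmetric_parameters(), H_O = 60)
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "symtip_params"))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .param_fields)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    params[names(over)] <- over
  }
  do.call(model_parameters, unclass(params))
}

#' Test whether a parameter set is system-symmetric
#'
#' System symmetry holds when the two functional groups have identical
#' trait values: the half-inhibition constants and the substrate production
#' constants are equal (all other traits are shared by construction) and the
#' background concentrations of the two substrates coincide.
#'
#' @param params A `symtip_params` object.
#' @return `TRUE` or `FALSE`.
#' @export
is_system_symmetric <- function(params) {
  stopifnot(inherits(params, "symtip_params"))
  params$H_S == params$H_O && params$p_O == params$p_S &&
    params$O_b == params$S_b
}

#' @export
print.symtip_params <- function(x, ...) {
  cat("Mutual-inhibition ecosystem model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " = ",
             format(v, digits = 6)), sep = "\n")
  cat(if (is_system_symmetric(x)) "  (system-symmetric)\n"
      else "  (system-asymmetric)\n")
  invisible(x)
}

#' System state vector
#'
#' @param N_CB Cyanobacteria density, cells/L.
#' @param N_SB Sulfur-reducing bacteria density, cells/L.
#' @param O Oxygen concentration, uM.
#' @param S Sulfide concentration, uM.
#' @param P Phosphorus concentration, uM.
#' @return A named numeric vector with components
#'   `N_CB`, `N_SB`, `O`, `S`, `P`.
#' @export
system_state <- function(N_CB, N_SB, O, S, P) {
  x <- c(N_CB = N_CB, N_SB = N_SB, O = O, S = S, P = P)
  if (!all(is.finite(x)) || any(x < 0))
    stop("all state components must be finite and nonnegative",
         call. = FALSE)
  x
}

#' Mirror a state across the oxic/anoxic symmetry
#'
#' Swaps the two functional groups and the two substrates:
#' `N_CB <-> N_SB` and `O <-> S`.  Phosphorus is self-symmetric.
#' Under a system-symmetric parameter set the model flow commutes with this
#' swap (together with a swap of the two diffusivities).
#'
#' @param state A named vector with components `N_CB`, `N_SB`, `O`, `S`,
#'   `P` -- a system state or any quantity indexed like one (for example a
#'   vector of time derivatives).
#' @return The mirrored vector.
#' @export
mirror_state <- function(state) {
  c(N_CB = unname(state["N_SB"]), N_SB = unname(state["N_CB"]),
    O = unname(state["S"]), S = unname(state["O"]),
    P = unname(state["P"]))
}

#' Write / read a parameter set as a flat key-value file
#'
#' One `key = value` pair per line, keys being the parameter field names.
#' Values are written in full double precision so the round trip is
#' lossless.
#'
#' @param params A `symtip_params` object.
#' @param path File path.
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` returns a `symtip_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "symtip_params"))
  lines <- sprintf("%s = %s", names(params),
                   vapply(params, function(v) sprintf("%.17g", v), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("malformed parameter file: expected 'key = value' lines",
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  missing <- setdiff(.param_fields, keys)
  if (length(missing))
    stop("parameter file is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- as.list(vals)
  names(p) <- keys
  do.call(model_parameters, p[.param_fields])
}
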