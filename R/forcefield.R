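# Parameter tables and the four pairwise energy terms: 6-12 dispersion/
# repulsion, directional 10-12 hydrogen bonding, Coulomb electrostatics with
# the Mehler-Solmajer distance-dependent dielectric, and Gaussian-damped
# pairwise desolvation.

# Published AutoDock 4 per-type parameters: Rii (sum of vdW radii of two like
# atoms, Angstrom), epsii (well depth, kcal/mol), Rij_hb / epsij_hb (10-12
# hydrogen-bond well for acceptor types), atomic volume (Angstrom^3) and
# solvation parameter.
.AD4_TYPES <- data.frame(
  row.names = c("H", "HD", "C", "A", "N", "NA", "OA", "S", "SA",
                "P", "F", "Cl", "Br", "I"),
  rii    = c(2.00, 2.00, 4.00, 4.00, 3.50, 3.50, 3.20, 4.00, 4.00,
             4.20, 3.09, 4.09, 4.33, 4.72),
  eps    = c(0.020, 0.020, 0.150, 0.150, 0.160, 0.160, 0.200, 0.200, 0.200,
             0.200, 0.080, 0.276, 0.389, 0.550),
  rii_hb = c(0, 0, 0, 0, 0, 1.9, 1.9, 0, 2.5, 0, 0, 0, 0, 0),
  eps_hb = c(0, 0, 0, 0, 0, 5.0, 5.0, 0, 1.0, 0, 0, 0, 0, 0),
  vol    = c(0.0000, 0.0000, 33.5103, 33.5103, 22.4493, 22.4493, 17.1573,
             33.5103, 33.5103, 38.7924, 15.4480, 35.8235, 42.5661, 55.0585),
  solpar = c(0.00051, 0.00051, -0.00143, -0.00052, -0.00162, -0.00162,
             -0.00251, -0.00214, -0.00214, -0.00110, -0.00110, -0.00110,
             -0.00110, -0.00110)
)

# Published AD4 term weights (bound-state calibration).
.AD4_WEIGHTS <- c(vdw = 0.1662, hbond = 0.1209, elec = 0.1406, sol = 0.1322)

# Mehler-Solmajer sigmoidal dielectric constants.
.MS_DIEL <- list(eps0 = 78.4, A = -8.5525, lambda = 0.003627, k = 7.7839)

.COULOMB_K <- 332.06  # e^2/Angstrom -> kcal/mol

#' Load force-field parameters
#'
#' Returns the built-in AutoDock-4-style parameter set (per-type vdW and
#' hydrogen-bond wells, atomic volumes, solvation parameters, term weights,
#' the Mehler-Solmajer dielectric constants, desolvation width, nonbonded
#' cutoff and clash threshold), optionally overridden from a plain-text file.
#'
#' The override file is whitespace-delimited.  Per-type lines are
#' \code{type Rii eps Rii_hb eps_hb vol solpar}; scalar lines are
#' \code{weight_vdw}, \code{weight_hbond}, \code{weight_elec},
#' \code{weight_sol}, \code{sigma}, \code{cutoff} or \code{clash_scale}
#' followed by a value.  Lines starting with \code{#} are ignored.
#'
#' @param override Optional path to an override file.
#' @param cutoff Nonbonded cutoff in Angstrom (default 8; hard truncation).
#' @param clash_scale Fraction of the pair equilibrium distance below which a
#'   contact is flagged as a clash (default 0.6).
#' @return An object of class \code{lig_forcefield}.
#' @export
load_forcefield <- function(override = NULL, cutoff = 8.0, clash_scale = 0.6) {
  p <- list(types = .AD4_TYPES, weights = .AD4_WEIGHTS, sigma = 3.5,
            dielectric = .MS_DIEL, cutoff = cutoff,
            clash_scale = clash_scale)
  class(p) <- "lig_forcefield"
  if (!is.null(override)) {
    if (!file.exists(override)) stop("override file not found: ", override)
    lines <- readLines(override, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      tok <- scan(text = ln, what = character(), quiet = TRUE)
      key <- tok[1]
      if (key %in% c("weight_vdw", "weight_hbond", "weight_elec",
                     "weight_sol")) {
        p$weights[[sub("^weight_", "", key)]] <- as.numeric(tok[2])
      } else if (key %in% c("sigma", "cutoff", "clash_scale")) {
        p[[key]] <- as.numeric(tok[2])
      } else if (key %in% rownames(p$types)) {
        if (length(tok) != 7L)
          stop("override line for type '", key, "' needs 6 numbers")
        p$types[key, ] <- as.numeric(tok[-1])
      } else {
        stop("unknown parameter key in override file: '", key, "'")
      }
    }
  }
  stopifnot(all(p$types$eps >= 0), all(p$types$rii > 0),
            all(p$weights > 0 | p$weights == 0), p$cutoff > 0)
  p
}

.ff_type_of <- function(x) {
  if (is.character(x)) x else if (!is.null(x$ff_type)) x$ff_type
  else stop("cannot determine force-field type")
}

.ff_row <- function(p, type) {
  if (!type %in% rownames(p$types)) stop("unknown atom type: ", type)
  p$types[type, ]
}

#' Pair equilibrium distance and well depth (Lorentz/geometric combination)
#'
#' \code{r_eq(i,j) = Rii/2 + Rjj/2}, \code{eps(i,j) = sqrt(eps_i eps_j)}.
#'
#' @param ti,tj Atom types (or typed-atom rows).
#' @param p A \code{lig_forcefield}.
#' @return List with \code{r_eq} and \code{eps}.
#' @export
combine_vdw <- function(ti, tj, p) {
  a <- .ff_row(p, .ff_type_of(ti)); b <- .ff_row(p, .ff_type_of(tj))
  list(r_eq = a$rii / 2 + b$rii / 2, eps = sqrt(a$eps * b$eps))
}

#' 6-12 Lennard-Jones dispersion/repulsion term
#'
#' \eqn{W_{vdw} (A/r^{12} - B/r^6)} with \eqn{A = \epsilon r_{eq}^{12}},
#' \eqn{B = 2 \epsilon r_{eq}^6}, so the minimum of depth
#' \eqn{-W_{vdw}\epsilon} sits exactly at \eqn{r_{eq}}.  Zero beyond the
#' cutoff (hard truncation).
#'
#' @param ti,tj Atom types (or typed-atom rows).
#' @param r Distance(s) in Angstrom (> 0).
#' @param p A \code{lig_forcefield}.
#' @return Energy in kcal/mol (vectorized over \code{r}).
#' @export
vdw_term <- function(ti, tj, r, p) {
  if (any(r <= 0)) stop("coincident atoms: r must be > 0")
  cm <- combine_vdw(ti, tj, p)
  A <- cm$eps * cm$r_eq^12
  B <- 2 * cm$eps * cm$r_eq^6
  e <- p$weights[["vdw"]] * (A / r^12 - B / r^6)
  e[r >= p$cutoff] <- 0
  e
}

#' Directional 10-12 hydrogen-bond term
#'
#' \eqn{E(t) W_{hb} (C/r^{12} - D/r^{10})} with \eqn{C = 5\epsilon_{hb}
#' r_{hb}^{12}}, \eqn{D = 6\epsilon_{hb} r_{hb}^{10}}, which places the
#' minimum of depth \eqn{-W_{hb}\epsilon_{hb}} at \eqn{r_{hb}}.  The well
#' parameters are those of the acceptor type; the distance is measured from
#' the polar hydrogen to the acceptor heavy atom.  The directionality factor
#' is \eqn{E(t) = \cos^2 t} for deviations \eqn{t < 90^\circ} from ideal
#' donor-H-acceptor geometry and 0 beyond.
#'
#' @param donor_h Polar-hydrogen type (\code{"HD"}) or typed-atom row.
#' @param acceptor Acceptor type (\code{"NA"}, \code{"OA"}, \code{"SA"}) or
#'   typed-atom row.
#' @param r Hydrogen-acceptor distance(s), Angstrom.
#' @param t_dev Deviation from ideal bonding geometry, degrees.
#' @param p A \code{lig_forcefield}.
#' @return Energy in kcal/mol.
#' @export
hbond_term <- function(donor_h, acceptor, r, t_dev, p) {
  th <- .ff_type_of(donor_h); ta <- .ff_type_of(acceptor)
  if (th != "HD") stop("donor_h must be a polar hydrogen (HD)")
  arow <- .ff_row(p, ta)
  if (arow$eps_hb <= 0) stop("type ", ta, " is not a hydrogen-bond acceptor")
  if (any(r <= 0)) stop("coincident atoms: r must be > 0")
  r0 <- arow$rii_hb; eps <- arow$eps_hb
  C <- 5 * eps * r0^12
  D <- 6 * eps * r0^10
  Et <- ifelse(t_dev < 90, cos(t_dev * pi / 180)^2, 0)
  e <- Et * p$weights[["hbond"]] * (C / r^12 - D / r^10)
  e[r >= p$cutoff] <- 0
  e
}

#' Mehler-Solmajer distance-dependent dielectric
#'
#' Sigmoidal screening function
#' \eqn{\epsilon(r) = A + B / (1 + k e^{-\lambda B r})} with
#' \eqn{A = -8.5525}, \eqn{B = \epsilon_0 - A}, \eqn{\epsilon_0 = 78.4},
#' \eqn{k = 7.7839}, \eqn{\lambda = 0.003627}: low-dielectric at contact
#' distances, approaching bulk-water permittivity at long range.
#'
#' @param r Distance(s) in Angstrom (>= 0).
#' @param p A \code{lig_forcefield}.
#' @return Dimensionless dielectric value(s).
#' @export
dielectric <- function(r, p) {
  d <- p$dielectric
  B <- d$eps0 - d$A
  d$A + B / (1 + d$k * exp(-d$lambda * B * r))
}

#' Coulomb electrostatic term with distance-dependent screening
#'
#' \eqn{W_{elec} \, 332.06 \, q_i q_j / (\epsilon(r) r)} kcal/mol.
#'
#' @param qi,qj Partial charges (elementary-charge units), or typed-atom rows
#'   with a \code{charge} field.
#' @param r Distance(s), Angstrom (> 0).
#' @param p A \code{lig_forcefield}.
#' @return Energy in kcal/mol.
#' @export
elec_term <- function(qi, qj, r, p) {
  if (is.list(qi)) qi <- qi$charge
  if (is.list(qj)) qj <- qj$charge
  if (any(r <= 0)) stop("coincident atoms: r must be > 0")
  e <- p$weights[["elec"]] * .COULOMB_K * qi * qj / (dielectric(r, p) * r)
  e[r >= p$cutoff] <- 0
  e
}

#' Gaussian pairwise desolvation term
#'
#' \eqn{W_{sol} (S_i V_j + S_j V_i) \exp(-r^2 / 2\sigma^2)} with the per-type
#' solvation parameter \eqn{S} and fragmental volume \eqn{V}, and
#' \eqn{\sigma = 3.5} Angstrom by default.
#'
#' @param ti,tj Atom types (or typed-atom rows).
#' @param r Distance(s), Angstrom (>= 0).
#' @param p A \code{lig_forcefield}.
#' @return Energy in kcal/mol.
#' @export
desolvation_term <- function(ti, tj, r, p) {
  a <- .ff_row(p, .ff_type_of(ti)); b <- .ff_row(p, .ff_type_of(tj))
  p$weights[["sol"]] * (a$solpar * b$vol + b$solpar * a$vol) *
    exp(-r^2 / (2 * p$sigma^2))
}

#' @export
print.lig_forcefield <- function(x, ...) {
  cat("lig_forcefield:", nrow(x$types), "atom types; weights",
      paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = " "),
      sprintf("; cutoff %.1f A, sigma %.1f A, clash < %.2f r_eq\n",
              x$cutoff, x$sigma, x$clash_scale))
  invisible(x)
}

#' Print the built-in parameter tables
#'
#' @param p A \code{lig_forcefield}.
#' @return The per-type parameter data frame, invisibly (printed as a side
#'   effect together with the scalar parameters).
#' @export
forcefield_table <- function(p = load_forcefield()) {
  print(p)
  print(p$types)
  invisible(p$types)
}
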