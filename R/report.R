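# Report generation: one-call structural/stability/classification analysis
# and simulation reports, used directly and by the command-line wrapper.

#' Full analysis report for a network
#'
#' Computes the structural profile (rank, molecularity, trivial species,
#' nontriviality certificate, kernel sign vector), the classification verdict
#' (the general trimolecular decision when it applies, else the planar
#' Andronov--Hopf classification, else the precondition checklist), and, when
#' rate constants are supplied, the positive equilibria and local stability
#' data.
#'
#' @param net a `crn_network`, or a string/character vector in the reaction
#'   text format.
#' @param kappa optional positive rate constants.
#' @return a list of class `crn_report` (JSON-serializable via
#'   [report_to_json()]).
#' @export
run_analyze <- function(net, kappa = NULL) {
  if (!inherits(net, "crn_network")) net <- parse_network(net)
  mp <- molecularity_profile(net)
  nt <- is_dynamically_nontrivial(net)
  rep <- list(
    network = format_network(net),
    species = net$species, n = net$n, m = net$m,
    rank = network_rank(net),
    molecularity = mp[c("max_source", "max_target")],
    quadratic = mp$is_quadratic,
    trivial_species = net$species[trivial_species(net)],
    dynamically_nontrivial = nt$status,
    nontriviality_witness = if (nt$status) nt$positive_kernel_vector else nt$separating_vector,
    sources_collinear = sources_collinear(net)
  )
  if (net$m == 3 && rep$rank == 2) {
    rep$kernel_sign_vector <- kernel_sign_vector(net)
  }
  rep$verdict <- tryCatch({
    if (net$m == 3 && mp$is_quadratic && mp$max_target <= 3) {
      classify_trimolecular_general(net)
    } else if (net$m == 3 && net$n == 2 && mp$is_quadratic) {
      hopf_verdict_planar(net)
    } else {
      NULL
    }
  }, error = function(e) NULL)
  if (!is.null(kappa)) {
    sys <- mass_action(net, kappa)
    rep$kappa <- sys$kappa
    if (net$m == 3 && rep$rank == 2) {
      eq <- positive_equilibria(sys)
      rep$equilibrium <- if (eq$exists) {
        list(x = eq$x, mu = eq$mu, unique = eq$unique, residual = eq$residual)
      } else list(exists = FALSE, reason = eq$reason)
      if (eq$exists) {
        if (net$n == 2) {
          pdt <- planar_det_tr(sys, eq)
          rep$stability <- pdt[c("det", "tr", "class")]
        } else {
          rj <- tryCatch(reduced_jacobian(sys, eq$x), error = function(e) NULL)
          if (!is.null(rj)) {
            rep$stability <- list(det_reduced = rj$det, det_sign = rj$det_sign,
                                  mu = rj$mu)
          }
        }
      }
    }
    rep$conserved <- lapply(conserved_quantities(sys), function(q) {
      q[setdiff(names(q), "value")]
    })
  }
  structure(rep, class = "crn_report")
}

#' @export
print.crn_report <- function(x, ...) {
  cat("network:\n"); cat(paste0("  ", x$network, collapse = "\n"), "\n")
  cat(sprintf("rank %d; source molecularity <= %d, target <= %d; %s\n",
              x$rank, x$molecularity$max_source, x$molecularity$max_target,
              if (x$dynamically_nontrivial) "dynamically nontrivial" else "dynamically trivial"))
  if (length(x$trivial_species)) {
    cat("trivial species:", paste(x$trivial_species, collapse = ", "), "\n")
  }
  if (!is.null(x$verdict)) print(x$verdict)
  if (!is.null(x$equilibrium) && isTRUE(x$equilibrium$unique)) {
    cat("equilibrium:", paste(signif(x$equilibrium$x, 6), collapse = ", "), "\n")
  }
  if (!is.null(x$stability)) {
    cat("stability:", paste(names(x$stability),
                            vapply(x$stability, function(v) paste(signif(unlist(v), 6), collapse = " "), ""),
                            sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#' @param rep a `crn_report` (or any list).
#' @return JSON string.
#' @export
report_to_json <- function(rep) {
  strip <- function(x) {
    if (inherits(x, "crn_verdict")) x <- unclass(x)
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::toJSON(strip(unclass(rep)), auto_unbox = TRUE, digits = NA,
                   null = "null", force = TRUE)
}

#' Simulate and report
#'
#' Integrates the system, reports conserved-quantity drift and the
#' periodicity verdict of the Poincare return map, and optionally writes the
#' trajectory as CSV.
#' @param net a `crn_network` or reaction text.
#' @param kappa positive rate constants.
#' @param x0 positive initial state.
#' @param t_end integration horizon.
#' @param csv optional path; write the trajectory (t, x1..xn) there.
#' @param ... passed to [simulate_system()].
#' @return list with `trajectory`, `drift`, `blowup`, `periodicity`.
#' @export
run_simulate <- function(net, kappa, x0, t_end, csv = NULL, ...) {
  if (!inherits(net, "crn_network")) net <- parse_network(net)
  sys <- mass_action(net, kappa)
  traj <- simulate_system(sys, x0, t_end, ...)
  per <- if (network_rank(net) == 2 && !attr(traj, "blowup")) {
    tryCatch(detect_periodicity(sys, x0, t_end = t_end),
             error = function(e) list(periodic = NA, reason = conditionMessage(e)))
  } else list(periodic = NA, reason = "rank != 2 or blow-up")
  if (!is.null(csv)) utils::write.csv(traj, csv, row.names = FALSE)
  list(trajectory = traj, drift = attr(traj, "drift"),
       blowup = attr(traj, "blowup"), periodicity = per)
}
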