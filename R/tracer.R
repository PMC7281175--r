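#' @name tracer_model
#' @title Atom-mapped [U-13C]glucose tracer model
#'
#' @description
#' The tracer module interprets mass-isotopologue measurements from
#' [U-13C]glucose labeling through a steady-state, atom-mapped model of
#' central carbon metabolism: glycolysis (GLC -> G6P -> F6P -> F16BP ->
#' DHAP/GAP -> 3PG -> PEP -> PYR -> LAC), the oxidative pentose phosphate
#' pathway (G6P -> Ru5P + CO2 from carbon 1), the non-oxidative PPP
#' (transketolase/transaldolase rearrangements of Ru5P/X5P/R5P/S7P/E4P/F6P/
#' GAP with standard atom maps), the TCA cycle (PYR -> AcCoA + CO2;
#' citrate synthase; two CO2 losses per turn, both from oxaloacetate
#' carbons; succinate and fumarate with 50/50 rotational scrambling), and
#' the citrate-malate shuttle (cytosolic citrate cleavage to acetyl-CoA +
#' oxaloacetate, reduction to malate, re-import into the mitochondrial
#' malate pool).
#'
#' Pool labeling is represented positionally: each metabolite with n
#' carbons carries a probability vector over its 2^n labeling states
#' (n <= 7, so at most 128 states). At metabolic steady state each pool's
#' isotopomer distribution is the flux-weighted mixture of its producing
#' reactions' atom-mapped substrate distributions, diluted by any
#' unlabeled influx; [simulate_isotopomers()] solves this fixed point and
#' marginalizes to mass isotopologues M+0..M+n, and [monte_carlo_oracle()]
#' verifies it by molecule-level stochastic atom tracking.
NULL

#' Build the default tracer network
#'
#' Constructs the atom-mapped reaction network described in
#' [tracer_model], parameterized by branch-flux fractions and dilution
#' pools.
#'
#' @param f_ppp fraction of glucose-6-phosphate consumption routed into the
#'   oxidative PPP (the remainder proceeds down glycolysis).
#' @param f_lactate,f_pdh,f_pc fractions of pyruvate consumption routed to
#'   lactate, to acetyl-CoA via pyruvate dehydrogenase, and to oxaloacetate
#'   via pyruvate carboxylase (default 0; the remainder covers other fates
#'   such as transamination). Must sum to <= 1. These shares set relative
#'   pool sizes for downstream products; in the steady-state pool formalism
#'   they do not change labeling patterns because lactate and acetyl-CoA
#'   each have a single producing reaction.
#' @param f_shuttle fraction of citrate consumption exported to the cytosol
#'   (ATP-citrate lyase / citrate-malate shuttle) rather than continuing
#'   around the TCA cycle.
#' @param tracer_purity fraction of the glucose pool that is fully labeled
#'   (M6) tracer; the rest is unlabeled.
#' @param dilution named numeric vector of per-metabolite unlabeled-influx
#'   fractions in `[0, 1]` (e.g. `c(OAA = 0.3)` for anaplerotic dilution);
#'   metabolites not named get 0.
#' @param shuttle include the citrate-malate shuttle reactions (disabling
#'   removes only the cytosolic citrate branch).
#' @return object of class `tracer_network`.
#' @examples
#' net <- build_network(f_ppp = 0.1, f_shuttle = 0.6)
#' net
#' @export
build_network <- function(f_ppp = 0.1, f_lactate = 0.3, f_pdh = 0.5,
                          f_pc = 0, f_shuttle = 0.3, tracer_purity = 1,
                          dilution = numeric(), shuttle = TRUE) {
  frac01 <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("parameter error: ", nm, " must lie in [0, 1]", call. = FALSE)
    x
  }
  frac01(f_ppp, "f_ppp"); frac01(f_lactate, "f_lactate")
  frac01(f_pdh, "f_pdh"); frac01(f_pc, "f_pc")
  frac01(f_shuttle, "f_shuttle"); frac01(tracer_purity, "tracer_purity")
  frac01(dilution, "dilution")
  if (f_lactate + f_pdh + f_pc > 1 + 1e-12)
    stop("parameter error: pyruvate branch fractions f_lactate + f_pdh + f_pc must sum to <= 1",
         call. = FALSE)

  n_carbons <- c(GLC = 6, G6P = 6, F6P = 6, F16BP = 6, DHAP = 3, GAP = 3,
                 PG3 = 3, PEP = 3, PYR = 3, LAC = 3, AcCoA = 2,
                 CIT = 6, AKG = 5, SUC = 4, FUM = 4, MAL = 4, OAA = 4,
                 Ru5P = 5, X5P = 5, R5P = 5, S7P = 7, E4P = 4,
                 CIT_cyt = 6, AcCoA_cyt = 2, OAA_cyt = 4, MAL_cyt = 4)
  if (!shuttle)
    n_carbons <- n_carbons[!names(n_carbons) %in%
                             c("CIT_cyt", "AcCoA_cyt", "OAA_cyt", "MAL_cyt")]
  bad <- setdiff(names(dilution), names(n_carbons))
  if (length(bad))
    stop("config error: dilution names unknown metabolite(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (f_shuttle > 0 && !shuttle)
    stop("config error: f_shuttle > 0 with the shuttle disabled", call. = FALSE)

  # a route: product <- substrates, with `map` giving for each product
  # carbon the (substrate index, substrate carbon) source, 0 meaning an
  # unlabeled entry; `co2` lists (substrate index, carbon) pairs lost as CO2
  route <- function(product, substrates, map, weight, name, co2 = NULL) {
    list(product = product, substrates = substrates, map = map,
         weight = weight, name = name, co2 = co2)
  }
  idm <- function(n) cbind(1L, seq_len(n))  # identity atom map

  glyc_flux <- 1 - f_ppp / 3   # F16BP flux per unit glucose uptake
  routes <- list(
    route("G6P", "GLC", idm(6), 1, "hexokinase"),
    # oxidative PPP: carbon 1 of G6P leaves as CO2
    route("Ru5P", "G6P", cbind(1L, 2:6), 1, "oxidative_ppp",
          co2 = cbind(1L, 1L)),
    route("X5P", "Ru5P", idm(5), 1, "epimerase"),
    route("R5P", "Ru5P", idm(5), 1, "isomerase"),
    # transketolase 1: X5P C1-C2 onto R5P; X5P C3-C5 -> GAP
    route("S7P", c("X5P", "R5P"),
          rbind(c(1L, 1L), c(1L, 2L), cbind(2L, 1:5)), 1, "transketolase1"),
    # transaldolase: S7P C1-C3 onto GAP -> F6P; S7P C4-C7 -> E4P
    route("E4P", "S7P", cbind(1L, 4:7), 1, "transaldolase"),
    route("F6P", "G6P", idm(6), 1 - f_ppp, "isomerase_glycolysis"),
    route("F6P", c("S7P", "GAP"),
          rbind(cbind(1L, 1:3), cbind(2L, 1:3)), f_ppp / 3, "transaldolase"),
    # transketolase 2: X5P C1-C2 onto E4P -> F6P
    route("F6P", c("X5P", "E4P"),
          rbind(c(1L, 1L), c(1L, 2L), cbind(2L, 1:4)), f_ppp / 3,
          "transketolase2"),
    route("F16BP", "F6P", idm(6), 1, "phosphofructokinase"),
    # aldolase: F16BP C1-C3 -> DHAP (reversed), C4-C6 -> GAP
    route("DHAP", "F16BP", cbind(1L, 3:1), 1, "aldolase"),
    route("GAP", "F16BP", cbind(1L, 4:6), glyc_flux, "aldolase"),
    route("GAP", "DHAP", idm(3), glyc_flux, "triose_isomerase"),
    route("GAP", "X5P", cbind(1L, 3:5), f_ppp / 3, "transketolase1"),
    route("GAP", "X5P", cbind(1L, 3:5), f_ppp / 3, "transketolase2"),
    route("PG3", "GAP", idm(3), 1, "lower_glycolysis"),
    route("PEP", "PG3", idm(3), 1, "enolase"),
    route("PYR", "PEP", idm(3), 1, "pyruvate_kinase"),
    route("LAC", "PYR", idm(3), 1, "lactate_dehydrogenase"),
    # PDH: pyruvate C1 leaves as CO2; AcCoA C1 = PYR C2 (carbonyl),
    # AcCoA C2 = PYR C3 (methyl)
    route("AcCoA", "PYR", rbind(c(1L, 2L), c(1L, 3L)), 1,
          "pyruvate_dehydrogenase", co2 = cbind(1L, 1L)),
    # citrate synthase: CIT = (OAA C4, OAA C3, OAA C2, AcCoA C2, AcCoA C1,
    # OAA C1)
    route("CIT", c("OAA", "AcCoA"),
          rbind(c(1L, 4L), c(1L, 3L), c(1L, 2L), c(2L, 2L), c(2L, 1L),
                c(1L, 1L)), 1, "citrate_synthase"),
    # isocitrate dehydrogenase: CO2 from CIT C6 (an OAA carbon)
    route("AKG", "CIT", cbind(1L, 1:5), 1, "isocitrate_dehydrogenase",
          co2 = cbind(1L, 6L)),
    # 2-oxoglutarate dehydrogenase: CO2 from AKG C1 (an OAA carbon)
    route("SUC", "AKG", cbind(1L, 2:5), 1, "akg_dehydrogenase",
          co2 = cbind(1L, 1L)),
    route("FUM", "SUC", idm(4), 1, "succinate_dehydrogenase"),
    route("MAL", "FUM", idm(4), 1 - f_shuttle, "fumarase"),
    route("OAA", "MAL", idm(4), 1 - f_pc, "malate_dehydrogenase"))
  if (f_pc > 0)
    routes <- c(routes, list(
      # pyruvate carboxylase: OAA C1-C3 = PYR C1-C3, C4 from (unlabeled) CO2
      route("OAA", "PYR", rbind(cbind(1L, 1:3), c(0L, 0L)), f_pc,
            "pyruvate_carboxylase")))
  if (shuttle)
    routes <- c(routes, list(
      route("CIT_cyt", "CIT", idm(6), 1, "citrate_export"),
      # ATP-citrate lyase inverts citrate synthase
      route("AcCoA_cyt", "CIT_cyt", rbind(c(1L, 5L), c(1L, 4L)), 1,
            "atp_citrate_lyase"),
      route("OAA_cyt", "CIT_cyt",
            rbind(c(1L, 6L), c(1L, 3L), c(1L, 2L), c(1L, 1L)), 1,
            "atp_citrate_lyase"),
      route("MAL_cyt", "OAA_cyt", idm(4), 1, "cytosolic_mdh"),
      route("MAL", "MAL_cyt", idm(4), f_shuttle, "malate_import")))

  dil <- stats::setNames(rep(0, length(n_carbons)), names(n_carbons))
  dil[names(dilution)] <- dilution
  # metabolites whose positional distribution is symmetrized (rotationally
  # scrambled) after production
  structure(
    list(n_carbons = n_carbons, routes = routes,
         scrambled = c("SUC", "FUM"),
         branch_fractions = c(f_ppp = f_ppp, f_lactate = f_lactate,
                              f_pdh = f_pdh, f_pc = f_pc,
                              f_shuttle = f_shuttle),
         dilution = dil, tracer_purity = tracer_purity,
         shuttle = shuttle),
    class = "tracer_network")
}

#' @export
print.tracer_network <- function(x, ...) {
  cat(sprintf("<tracer_network> %d metabolites, %d reactions%s\n",
              length(x$n_carbons), length(x$routes),
              if (x$shuttle) " (citrate-malate shuttle on)" else ""))
  cat("branch fractions:",
      paste(sprintf("%s=%.2g", names(x$branch_fractions),
                    x$branch_fractions), collapse = ", "), "\n")
  cat(sprintf("tracer purity (glucose M6 fraction): %.2g\n", x$tracer_purity))
  d <- x$dilution[x$dilution > 0]
  if (length(d))
    cat("dilution:", paste(sprintf("%s=%.2g", names(d), d), collapse = ", "), "\n")
  invisible(x)
}

# routes grouped by product with normalized weights
producer_table <- function(network) {
  prods <- unique(vapply(network$routes, `[[`, "", "product"))
  out <- lapply(prods, function(p) {
    rs <- Filter(function(r) r$product == p, network$routes)
    w <- vapply(rs, `[[`, 0, "weight")
    if (sum(w) <= 0) return(NULL)
    list(routes = rs, weights = w / sum(w))
  })
  stats::setNames(out, prods)
}

# index map (1-based) from joint substrate labeling states to the product
# state, for one route; substrate state s encodes carbon c labeled as bit
# 2^(c-1)
route_state_map <- function(route, n_carbons) {
  ns <- n_carbons[route$substrates]
  n_joint <- prod(2^ns)
  joint <- seq_len(n_joint) - 1L
  # decompose the joint index into per-substrate states (substrate 1 varies
  # fastest)
  states <- matrix(0L, n_joint, length(ns))
  rem <- joint
  for (i in seq_along(ns)) {
    states[, i] <- rem %% (2^ns[i])
    rem <- rem %/% (2^ns[i])
  }
  prod_state <- integer(n_joint)
  for (pc in seq_len(nrow(route$map))) {
    src <- route$map[pc, ]
    if (src[1] == 0L) next  # unlabeled entry carbon
    bit <- bitwAnd(states[, src[1]], bitwShiftL(1L, src[2] - 1L)) > 0L
    prod_state <- prod_state + bitwShiftL(1L, pc - 1L) * as.integer(bit)
  }
  prod_state + 1L
}

reverse_perm <- function(n) {
  s <- 0:(2^n - 1L)
  out <- integer(length(s))
  for (c in seq_len(n)) {
    bit <- bitwAnd(s, bitwShiftL(1L, c - 1L)) > 0L
    out <- out + bitwShiftL(1L, n - c) * as.integer(bit)
  }
  out + 1L
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Solve steady-state isotopomer distributions
#'
#' Fixed-point iteration on positional isotopomer distributions: each
#' metabolite's distribution is updated to the flux-weighted mixture of its
#' producing routes' atom-mapped substrate distributions (joint substrate
#' states assumed independent across pools), mixed with its unlabeled
#' dilution influx; succinate and fumarate are rotationally symmetrized.
#' Iteration stops when the largest absolute change of any state
#' probability falls below `tolerance`.
#'
#' @param network a [build_network()] object.
#' @param tolerance convergence threshold on state probabilities.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return named list of `isotopologue_vector` objects (one per
#'   metabolite): `metabolite_id`, `n_carbons`, `fractions` (M+0..M+n,
#'   summing to 1). The positional distributions are attached as attribute
#'   `"positional"`.
#' @examples
#' sim <- simulate_isotopomers(build_network(f_ppp = 0, f_shuttle = 0,
#'                                           tracer_purity = 1))
#' sim$PYR$fractions  # all mass in M+3
#' @export
simulate_isotopomers <- function(network, tolerance = 1e-10,
                                 max_iter = 1000L) {
  stopifnot(inherits(network, "tracer_network"))
  nc <- network$n_carbons
  producers <- producer_table(network)
  maps <- lapply(names(producers), function(p)
    lapply(producers[[p]]$routes, route_state_map, n_carbons = nc))
  names(maps) <- names(producers)
  scramble <- lapply(stats::setNames(nm = intersect(network$scrambled,
                                                    names(nc))),
                     function(m) reverse_perm(nc[[m]]))

  dist <- lapply(stats::setNames(nm = names(nc)), function(m) {
    d <- numeric(2^nc[[m]]); d[1] <- 1; d
  })
  # fixed source pool: tracer + unlabeled glucose
  glc <- numeric(2^nc[["GLC"]])
  glc[1] <- 1 - network$tracer_purity
  glc[2^nc[["GLC"]]] <- glc[2^nc[["GLC"]]] + network$tracer_purity
  dist$GLC <- glc

  order_m <- intersect(c("G6P", "Ru5P", "X5P", "R5P", "S7P", "E4P", "F6P",
                         "F16BP", "DHAP", "GAP", "PG3", "PEP", "PYR", "LAC",
                         "AcCoA", "CIT", "AKG", "SUC", "FUM",
                         "CIT_cyt", "AcCoA_cyt", "OAA_cyt", "MAL_cyt",
                         "MAL", "OAA"), names(producers))
  e0 <- function(n) { d <- numeric(2^n); d[1] <- 1; d }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in order_m) {
      pr <- producers[[m]]
      mix <- numeric(2^nc[[m]])
      for (i in seq_along(pr$routes)) {
        r <- pr$routes[[i]]
        joint <- dist[[r$substrates[1]]]
        if (length(r$substrates) > 1L)
          for (s in r$substrates[-1]) joint <- as.vector(outer(joint, dist[[s]]))
        contrib <- numeric(2^nc[[m]])
        agg <- rowsum(joint, maps[[m]][[i]])
        contrib[as.integer(rownames(agg))] <- agg[, 1]
        mix <- mix + pr$weights[i] * contrib
      }
      d <- network$dilution[[m]]
      if (d > 0) mix <- (1 - d) * mix + d * e0(nc[[m]])
      if (m %in% names(scramble)) mix <- (mix + mix[scramble[[m]]]) / 2
      delta <- max(delta, max(abs(mix - dist[[m]])))
      dist[[m]] <- mix
    }
    if (delta < tolerance) break
  }
  if (delta >= tolerance)
    stop(sprintf("tracer solver did not converge in %d iterations (residual %.3g)",
                 max_iter, delta), call. = FALSE)
  out <- lapply(names(dist), function(m)
    isotopologue_vector(m, nc[[m]], marginalize_mass(dist[[m]], nc[[m]])))
  names(out) <- names(dist)
  attr(out, "positional") <- dist
  attr(out, "iterations") <- iter
  out
}

marginalize_mass <- function(d, n) {
  k <- popcount(seq_along(d) - 1L)
  as.vector(rowsum(d, k))
}

#' Construct a mass-isotopologue fraction vector
#' @param metabolite_id metabolite name.
#' @param n_carbons number of carbons.
#' @param fractions numeric vector of length `n_carbons + 1` (M+0..M+n),
#'   non-negative, summing to 1 within 1e-9.
#' @return object of class `isotopologue_vector`.
#' @export
isotopologue_vector <- function(metabolite_id, n_carbons, fractions) {
  if (length(fractions) != n_carbons + 1L)
    stop("validation error: need n_carbons + 1 fractions", call. = FALSE)
  if (any(fractions < -1e-12))
    stop("validation error: negative isotopologue fraction", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("validation error: fractions of ", metabolite_id,
         " sum to ", format(sum(fractions)), ", not 1", call. = FALSE)
  structure(list(metabolite_id = metabolite_id,
                 n_carbons = as.integer(n_carbons),
                 fractions = stats::setNames(pmax(fractions, 0),
                                             paste0("M", 0:n_carbons))),
            class = "isotopologue_vector")
}

#' @export
print.isotopologue_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<%s> ", x$metabolite_id))
  cat(paste(sprintf("%s=%.*f", names(x$fractions), digits, x$fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' Molecule-level Monte-Carlo oracle for the tracer model
#'
#' Independent stochastic check of [simulate_isotopomers()]: each pool is a
#' population of `n_molecules` individually tracked molecules (logical
#' label vector per carbon). Pools are repeatedly resampled from their
#' producing routes — per molecule, a route is drawn by flux weight,
#' substrate molecules are drawn uniformly from the current pools and the
#' atom map applied, with dilution draws replaced by unlabeled molecules —
#' until the population distributions stabilize. Agreement with the
#' deterministic solver is expected within ~3/sqrt(n_molecules) per mass
#' fraction.
#'
#' @param network a [build_network()] object.
#' @param n_molecules molecules per pool (>= 1e4 recommended).
#' @param seed integer seed; results are reproducible under a fixed seed.
#' @param n_iter number of burn-in resampling sweeps before tallying.
#' @param n_tally number of post-burn-in sweeps over which mass-isotopologue
#'   counts are averaged (reduces the resampling variance of the estimate).
#' @return named list of `isotopologue_vector`, as the solver.
#' @export
monte_carlo_oracle <- function(network, n_molecules = 1e5, seed = 1,
                               n_iter = 40L, n_tally = 20L) {
  stopifnot(inherits(network, "tracer_network"))
  set.seed(seed)
  nc <- network$n_carbons
  producers <- producer_table(network)
  n <- as.integer(n_molecules)

  pools <- lapply(stats::setNames(nm = names(nc)), function(m)
    matrix(FALSE, n, nc[[m]]))
  pools$GLC <- matrix(stats::runif(n) < network$tracer_purity, n, 1)[, rep(1, nc[["GLC"]]), drop = FALSE]

  order_m <- intersect(c("G6P", "Ru5P", "X5P", "R5P", "S7P", "E4P", "F6P",
                         "F16BP", "DHAP", "GAP", "PG3", "PEP", "PYR", "LAC",
                         "AcCoA", "CIT", "AKG", "SUC", "FUM",
                         "CIT_cyt", "AcCoA_cyt", "OAA_cyt", "MAL_cyt",
                         "MAL", "OAA"), names(producers))

  tally <- lapply(stats::setNames(nm = names(nc)), function(m)
    numeric(nc[[m]] + 1L))
  for (iter in seq_len(n_iter + n_tally)) {
    for (m in order_m) {
      pr <- producers[[m]]
      new_pool <- matrix(FALSE, n, nc[[m]])
      ridx <- if (length(pr$weights) == 1L) rep(1L, n)
              else sample.int(length(pr$weights), n, replace = TRUE,
                              prob = pr$weights)
      for (i in seq_along(pr$routes)) {
        rows <- which(ridx == i)
        if (!length(rows)) next
        r <- pr$routes[[i]]
        subs <- lapply(r$substrates, function(s)
          pools[[s]][sample.int(n, length(rows), replace = TRUE), ,
                     drop = FALSE])
        for (pc in seq_len(nrow(r$map))) {
          src <- r$map[pc, ]
          if (src[1] == 0L) next
          new_pool[rows, pc] <- subs[[src[1]]][, src[2]]
        }
      }
      d <- network$dilution[[m]]
      if (d > 0) {
        unl <- stats::runif(n) < d
        new_pool[unl, ] <- FALSE
      }
      if (m %in% network$scrambled) {
        flip <- stats::runif(n) < 0.5
        new_pool[flip, ] <- new_pool[flip, rev(seq_len(nc[[m]])), drop = FALSE]
      }
      pools[[m]] <- new_pool
    }
    if (iter > n_iter)
      for (m in names(pools))
        tally[[m]] <- tally[[m]] +
          tabulate(rowSums(pools[[m]]) + 1L, nbins = nc[[m]] + 1L)
  }
  out <- lapply(names(pools), function(m) {
    f <- tally[[m]] / sum(tally[[m]])
    isotopologue_vector(m, nc[[m]], f)
  })
  stats::setNames(out, names(pools))
}

#' Labeled fraction of an isotopologue
#'
#' The measurement convention for labeling tables: per sample, the fraction
#' is the peak area of the M+k isotopologue divided by the total peak-area
#' pool of that metabolite (all isotopologues); group means are averages
#' over samples.
#'
#' @param table an [isotopologue_table()] with a group design attached (or
#'   pass `by_group = FALSE` for per-sample output only).
#' @param metabolite metabolite id.
#' @param mass_shift k of the M+k isotopologue.
#' @param by_group also compute group means (requires groups).
#' @return list of class `labeled_fraction_record`: `metabolite_id`,
#'   `mass_shift`, `per_sample` (named fractions; `NA` with a flag for
#'   samples whose total area is zero), `flagged_samples`, and `group_mean`
#'   when grouped.
#' @examples
#' tab <- isotopologue_table(
#'   data.frame(metabolite = "citrate", mass_shift = c(0, 2, 3),
#'              sample = "s1", area = c(900, 100, 0)),
#'   n_carbons = c(citrate = 6))
#' labeled_fraction(tab, "citrate", 2, by_group = FALSE)$per_sample  # 0.1
#' @export
labeled_fraction <- function(table, metabolite, mass_shift,
                             by_group = TRUE) {
  stopifnot(inherits(table, "isotopologue_table"))
  rec <- table[table$metabolite == metabolite, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("validation error: metabolite '", metabolite, "' not in table",
         call. = FALSE)
  samples <- unique(rec$sample)
  total <- tapply(rec$area, rec$sample, sum)[samples]
  num <- sapply(samples, function(s) {
    i <- rec$sample == s & rec$mass_shift == mass_shift
    if (any(i)) sum(rec$area[i]) else 0
  })
  frac <- ifelse(total > 0, num / total, NA_real_)
  names(frac) <- samples
  out <- list(metabolite_id = metabolite, mass_shift = mass_shift,
              per_sample = frac,
              flagged_samples = samples[is.na(frac)])
  if (by_group) {
    groups <- attr(table, "groups")
    if (is.null(groups))
      stop("design error: table has no group design; pass by_group = FALSE",
           call. = FALSE)
    g <- groups[samples]
    gm <- tapply(frac, g, mean, na.rm = TRUE)
    out$group_mean <- stats::setNames(as.numeric(gm), names(gm))
  }
  structure(out, class = "labeled_fraction_record")
}

#' Summarize all labeled fractions of a table
#'
#' Convenience wrapper over [labeled_fraction()]: one row per (metabolite,
#' mass shift, group) with the group-mean labeled fraction.
#'
#' @param table an [isotopologue_table()] with groups.
#' @return data.frame with columns metabolite, mass_shift, group,
#'   mean_fraction.
#' @export
labeled_fraction_table <- function(table) {
  nc <- attr(table, "n_carbons")
  rows <- list()
  for (m in unique(table$metabolite)) {
    for (k in 0:nc[[m]]) {
      rec <- labeled_fraction(table, m, k, by_group = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(metabolite = m, mass_shift = k,
                   group = names(rec$group_mean),
                   mean_fraction = as.numeric(rec$group_mean),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Natural-abundance correction of an isotopologue vector
#'
#' Observed mass fractions are the convolution of the tracer-derived
#' fractions with binomial natural 13C abundance over the unlabeled
#' carbons: `observed = M %*% true` with
#' `M[i, j] = choose(n - j, i - j) p13^(i - j) (1 - p13)^(n - i)`
#' (0-based i, j). Correction solves this triangular system, clips small
#' negative values and renormalizes. Off by default in reporting functions,
#' matching the raw [labeled]/[total] presentation convention.
#'
#' @param vector an [isotopologue_vector()].
#' @param p13 natural 13C abundance (default 0.0107; must be <= 0.05).
#' @param enabled return the input untouched when `FALSE`.
#' @return corrected `isotopologue_vector`.
#' @export
natural_abundance_correct <- function(vector, p13 = 0.0107, enabled = TRUE) {
  stopifnot(inherits(vector, "isotopologue_vector"))
  if (!enabled) return(vector)
  if (p13 < 0 || p13 > 0.05)
    stop("parameter error: p13 must lie in [0, 0.05]", call. = FALSE)
  M <- na_matrix(vector$n_carbons, p13)
  corrected <- solve(M, vector$fractions)
  corrected <- pmax(corrected, 0)
  corrected <- corrected / sum(corrected)
  isotopologue_vector(vector$metabolite_id, vector$n_carbons, corrected)
}

#' Forward natural-abundance convolution
#'
#' Applies the binomial natural-abundance operator to a tracer-only
#' isotopologue vector, producing the mass pattern a spectrometer would
#' observe; the forward counterpart (and test oracle) of
#' [natural_abundance_correct()].
#'
#' @inheritParams natural_abundance_correct
#' @return convolved `isotopologue_vector`.
#' @export
natural_abundance_convolve <- function(vector, p13 = 0.0107) {
  stopifnot(inherits(vector, "isotopologue_vector"))
  M <- na_matrix(vector$n_carbons, p13)
  isotopologue_vector(vector$metabolite_id, vector$n_carbons,
                      drop(M %*% vector$fractions))
}

na_matrix <- function(n, p13) {
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) for (i in j:n)
    M[i + 1L, j + 1L] <- choose(n - j, i - j) * p13^(i - j) *
      (1 - p13)^(n - i)
  M
}

#' Audit carbon conservation of a tracer network
#'
#' For every route, checks that each product carbon maps from exactly one
#' substrate carbon (or a designated unlabeled entry) and that substrate
#' carbons are each either passed to the product or designated as CO2
#' loss / side-product carbons. Returns a per-route accounting.
#'
#' @param network a [build_network()] object.
#' @return data.frame with one row per route: product, substrates, carbons
#'   in, carbons to product, carbons to CO2, and whether the route is part
#'   of a multi-product reaction (where remaining carbons leave via the
#'   sibling product).
#' @export
audit_network <- function(network) {
  rows <- lapply(network$routes, function(r) {
    n_in <- sum(network$n_carbons[r$substrates])
    to_prod <- sum(r$map[, 1] != 0L)
    data.frame(reaction = r$name, product = r$product,
               substrates = paste(r$substrates, collapse = "+"),
               carbons_in = n_in, carbons_to_product = to_prod,
               carbons_to_co2 = if (is.null(r$co2)) 0L else nrow(r$co2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
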