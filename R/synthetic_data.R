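#' Generative coefficient table of the factorial response models
#'
#' The 8-term coefficient vectors (on the [0, 1] range-scaled response
#' scale) of the ten lipid subclasses whose extraction depends
#' significantly on the MAE conditions; non-significant entries are
#' zero. These vectors are the generative truth of
#' [gen_ffd_responses()]: refitting noiseless responses generated from
#' them returns them exactly.
#'
#' @return 8 x 10 numeric matrix, rows `b0...b123`, columns the ten
#'   modelled subclasses.
#' @export
mae_coefficient_table <- function() {
  responses <- c("Cer", "Hex1Cer", "LPC", "LPE", "LPI", "LPS",
                 "PC", "PE", "PI", "TG_2OX")
  m <- matrix(
    c(# Cer    Hex1Cer  LPC     LPE     LPI     LPS     PC      PE      PI      TG_2OX
      0.474,  0.453,  0.335,  0.428,  0.364,  0.343,  0.502,  0.512,  0.425,  0.115,  # b0
     -0.119,  0.000,  0.334,  0.344,  0.345,  0.331, -0.241, -0.238, -0.286,  0.141,  # b1
     -0.112, -0.203,  0.000,  0.000,  0.021,  0.000, -0.114, -0.115, -0.131,  0.000,  # b2
      0.000,  0.000,  0.117,  0.000,  0.096,  0.109, -0.065, -0.071,  0.000,  0.137,  # b3
      0.000,  0.000,  0.000,  0.000,  0.034,  0.000, -0.061,  0.000,  0.000,  0.000,  # b12
      0.000,  0.000,  0.115,  0.000,  0.096,  0.121, -0.066,  0.000,  0.000,  0.000,  # b13
      0.236,  0.166,  0.000,  0.000, -0.072,  0.000,  0.115,  0.090,  0.000,  0.000,  # b23
      0.000, -0.212,  0.000,  0.000, -0.081, -0.075, -0.080, -0.076,  0.000,  0.000), # b123
    nrow = 8, byrow = TRUE, dimnames = list(ffd_terms(), responses))
  m
}

#' The 18 lipid-subclass response names of the workflow
#'
#' Ten subclasses carry a factorial model ([mae_coefficient_table()]);
#' the remaining eight show no significant dependence on the extraction
#' conditions and are generated with intercept-only models.
#'
#' @return Character vector of length 18.
#' @export
mae_response_names <- function() {
  c(colnames(mae_coefficient_table()),
    "TG", "TG_1OX", "DG", "DG_OX", "ChE", "BisMePA", "SM", "Hex2Cer")
}

# intercepts of the non-modelled responses (scaled-response units)
flat_intercepts <- function() {
  c(TG = 0.52, TG_1OX = 0.48, DG = 0.50, DG_OX = 0.46,
    ChE = 0.49, BisMePA = 0.51, SM = 0.47, Hex2Cer = 0.53)
}

#' Configuration of the synthetic-data generators
#'
#' Bundles the parameters shared by the generators. `noise_sd` is the
#' standard deviation of the i.i.d. Gaussian noise added to generated
#' factorial responses, on the [0, 1]-scaled response scale; the default
#' 0.01 is small relative to the coefficient magnitudes so significance
#' patterns are stable. Identical configurations (including the seed)
#' produce identical output.
#'
#' @param seed Integer seed.
#' @param noise_sd Response noise sd (scaled units).
#' @param coefficients Response-by-term generative coefficient matrix
#'   (default [mae_coefficient_table()] plus intercept-only columns for
#'   the remaining subclasses).
#' @param n_per_solvent Extraction replicates per solvent mixture in the
#'   screening generator (default 12).
#' @param qc_rsd_pct Named vector of true RSD% per deuterated standard
#'   for [gen_qc_table()].
#' @param qc_replicates QC replicate count.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, noise_sd = 0.01, coefficients = NULL,
                             n_per_solvent = 12,
                             qc_rsd_pct = c(d7_LPC = 4, d7_PC = 5, d7_PE = 6,
                                            d7_SM = 8, d7_TG = 10),
                             qc_replicates = 6) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(coefficients)) {
    coefficients <- mae_coefficient_table()
    flat <- flat_intercepts()
    extra <- matrix(0, 8, length(flat),
                    dimnames = list(ffd_terms(), names(flat)))
    extra["b0", ] <- flat
    coefficients <- cbind(coefficients, extra)
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 coefficients = coefficients,
                 n_per_solvent = as.integer(n_per_solvent),
                 qc_rsd_pct = qc_rsd_pct,
                 qc_replicates = as.integer(qc_replicates)),
            class = "generator_config")
}

#' Generate factorial response tables from the coefficient models
#'
#' For every response column of the configuration's coefficient table,
#' `Y = X beta + N(0, noise_sd)` where X is the 8-term model matrix of
#' the design in coded units. With `noise_sd = 0` the responses are an
#' exact polynomial of the design and refitting recovers the
#' coefficients to machine precision.
#'
#' @param design A three-factor `design_table`.
#' @param config A `generator_config`.
#' @return Data frame of responses (runs x subclasses), row names the
#'   design run ids.
#' @export
gen_ffd_responses <- function(design, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  X <- ffd_model_matrix(design)
  B <- config$coefficients
  stopifnot(identical(rownames(B), ffd_terms()))
  local_seed(config$seed, {
    Y <- X %*% B
    if (config$noise_sd > 0) {
      Y <- Y + matrix(stats::rnorm(length(Y), 0, config$noise_sd), nrow(Y))
    }
    out <- as.data.frame(Y)
    rownames(out) <- design$run_id
    out
  })
}

#' Generate a solvent-screening abundance table
#'
#' Emulates the structure of the solvent comparison: three solvent
#' mixtures (methanol/ethyl acetate ME, ethanol/ethyl acetate EE,
#' isopropanol/ethyl acetate IE), `n_per_solvent` extraction replicates
#' each, 18 lipid-subclass abundance columns spanning several orders of
#' magnitude. Group structure is built on a shared latent extraction
#' axis: ME and IE sit at the ends with tight within-group spread, EE
#' between them (closer to ME) with a larger spread, so ME and IE
#' separate cleanly while EE overlaps its neighbours — and the relative
#' difference between ME and EE group means stays below 20% for every
#' subclass by construction.
#'
#' @param config A `generator_config`.
#' @return Data frame with `sample_id`, `solvent` (ME/EE/IE) and one
#'   abundance column per subclass in [mae_response_names()] order.
#' @export
gen_solvent_screening <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_per_solvent
  if (n < 4) stop("n_per_solvent must be >= 4", call. = FALSE)
  subclasses <- mae_response_names()
  p <- length(subclasses)
  base <- 10^seq(2, 5, length.out = p)           # abundance magnitudes
  u1 <- rep_len(c(1, -1), p)                     # main extraction axis pattern
  u2 <- rep_len(c(1, 0, -1), p)                  # EE-specific signature pattern
  tau <- 0.2                                     # axis gain; ME/EE log-ratio is
                                                 # 0.2*0.45 + 0.03 = 0.12 < log(1.2)
  ee_sig <- 0.03
  centers <- c(ME = -1, EE = -0.55, IE = 1)
  spread <- c(ME = 0.18, EE = 0.35, IE = 0.18)
  local_seed(config$seed + 1L, {
    solvent <- rep(names(centers), each = n)
    z <- stats::rnorm(3 * n, centers[solvent], spread[solvent])
    samp_fac <- exp(stats::rnorm(3 * n, 0, 0.05))  # per-extraction recovery
    A <- matrix(0, 3 * n, p, dimnames = list(NULL, subclasses))
    for (s in seq_len(p)) {
      A[, s] <- base[s] * exp(tau * u1[s] * z +
                                ee_sig * u2[s] * (solvent == "EE")) *
        samp_fac * exp(stats::rnorm(3 * n, 0, 0.05))
    }
    out <- data.frame(sample_id = sprintf("%s_%02d", solvent,
                                          unlist(lapply(1:3, function(g) 1:n))),
                      solvent = solvent, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(A))
  })
}

#' Generate replicate QC peak areas for deuterated standards
#'
#' Replicate areas are drawn as `Normal(mean, mean * rsd/100)` per
#' standard, with the true RSD% taken from the configuration.
#'
#' @param config A `generator_config`.
#' @return Named list of numeric replicate vectors, one per standard.
#' @export
gen_qc_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed + 2L, {
    means <- 1e5 * seq(1, 2, length.out = length(config$qc_rsd_pct))
    out <- lapply(seq_along(config$qc_rsd_pct), function(i) {
      stats::rnorm(config$qc_replicates, means[i],
                   means[i] * config$qc_rsd_pct[i] / 100)
    })
    stats::setNames(out, names(config$qc_rsd_pct))
  })
}

# --- deterministic identification fixture ---------------------------------

# expand a named count vector into an ordered token vector
expand_pool <- function(counts) rep(names(counts), counts)

# pair position pools into unique chain tuples, deterministically: the
# first position is taken in pool order; the remaining positions are
# drawn from their multisets by a balanced greedy rule (maximize the
# product of remaining counts over unused tuples), which spreads
# high-multiplicity chains across as many prefixes as possible
pair_unique <- function(pools) {
  m <- length(pools)
  n <- length(pools[[1]])
  stopifnot(all(lengths(pools) == n), m %in% c(2L, 3L))
  first <- pools[[1]]
  rem <- lapply(pools[-1], function(p) {
    tab <- table(p)
    stats::setNames(as.integer(tab), names(tab))
  })
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- matrix("", n, m)
  for (i in seq_len(n)) {
    best <- NULL; best_score <- -1
    for (v2 in names(rem[[1]])[rem[[1]] > 0L]) {
      if (m == 2L) {
        key <- paste(first[i], v2, sep = "/")
        if (!is.null(seen[[key]])) next
        if (rem[[1]][[v2]] > best_score) {
          best <- v2; best_score <- rem[[1]][[v2]]
        }
      } else {
        for (v3 in names(rem[[2]])[rem[[2]] > 0L]) {
          key <- paste(first[i], v2, v3, sep = "/")
          if (!is.null(seen[[key]])) next
          score <- rem[[1]][[v2]] * rem[[2]][[v3]]
          if (score > best_score) {
            best <- c(v2, v3); best_score <- score
          }
        }
      }
    }
    if (is.null(best)) stop("could not build a unique chain tuple at row ", i)
    out[i, ] <- c(first[i], best)
    for (j in seq_along(best)) {
      rem[[j]][[best[j]]] <- rem[[j]][[best[j]]] - 1L
    }
    seen[[paste(out[i, ], collapse = "/")]] <- TRUE
  }
  out
}

fixture_species <- function(names, adduct, ion_mode, grades) {
  lapply(seq_along(names), function(i) {
    parse_lipid_name(names[i],
                     adduct = if (length(adduct) == 1L) adduct else adduct[i],
                     ion_mode = ion_mode,
                     grade = grades[(i - 1L) %% length(grades) + 1L])
  })
}

#' Deterministic synthetic lipid identification fixture
#'
#' Builds, without any randomness, an identification table with the
#' species inventory of a mozzarella MAE extract: 449 species in 18
#' reporting subclasses, including 322 TG whose per-position saturation
#' tallies are sn-1 274 SFA / 48 MUFA / 0 PUFA and sn-2 205 / 101 / 16,
#' 24 oxidized TG (13 single-, 11 double-oxygen) and 1 oxidized DG of
#' which six match a non-oxidized parent, 39 DG (sn-1 87% SFA / 13%
#' MUFA), and the minor sphingolipid and (lyso)phospholipid classes with
#' their adducts and ion modes. Chains are drawn from the fatty-acid
#' vocabulary of dairy lipids (4:0 through 24:0, 18:1, 18:2, 18:3,
#' 20:4, 20:5, 22:5, sphingoid bases d16:1/d18:1). The fixture is
#' synthetic: it reproduces the inventory-level tallies, not any real
#' identification export.
#'
#' @return List of `lipid_species`.
#' @export
gen_lipid_fixture <- function() {
  # sn-1: 274 SFA / 48 MUFA / 0 PUFA; 46% S-C, 10% M-C, 44% L-C;
  # butyric acid leads with 87/322 = 27% of TG
  sn1 <- expand_pool(c("4:0" = 87, "6:0" = 25, "8:0" = 20, "10:0" = 16,
                       "14:0" = 22, "15:0" = 10,
                       "16:0" = 74, "17:0" = 20, "18:1" = 48))
  # sn-2: 205 SFA / 101 MUFA / 16 PUFA; 34% S-C, 20% M-C, 46% L-C
  sn2 <- expand_pool(c("4:0" = 50, "6:0" = 24, "8:0" = 20, "10:0" = 16,
                       "14:0" = 30, "15:0" = 20, "14:1" = 14,
                       "16:0" = 30, "17:0" = 15, "16:1" = 17,
                       "18:1" = 70, "18:2" = 16))
  # sn-3: roughly equal SFA/MUFA/PUFA; 5% S-C, 15% M-C, 80% L-C
  sn3 <- expand_pool(c("4:0" = 10, "6:0" = 6, "14:0" = 24, "15:0" = 12,
                       "14:1" = 12, "16:0" = 30, "17:0" = 13, "16:1" = 15,
                       "18:1" = 92, "18:2" = 60, "18:3" = 30,
                       "20:4" = 6, "20:5" = 6, "22:5" = 6))
  tg_chains <- pair_unique(list(sn1, sn2, sn3))
  tg_names <- apply(tg_chains, 1, function(r)
    paste0("TG(", paste(r, collapse = "/"), ")"))
  tg_adducts <- rep("+NH4", length(tg_names))
  tg_adducts[seq_along(tg_names) %% 5L == 0L] <- "+Na"
  tg <- fixture_species(tg_names, tg_adducts, "positive", c("A", "B", "A", "C"))

  # DG sn-1: 34 SFA (87%) / 5 MUFA (13%) / 0 PUFA; sn-2: 17/10/12
  dg1 <- expand_pool(c("4:0" = 8, "6:0" = 5, "8:0" = 4, "14:0" = 4,
                       "16:0" = 9, "17:0" = 4, "18:1" = 5))
  dg2 <- expand_pool(c("4:0" = 3, "12:0" = 2, "14:0" = 6, "15:0" = 3,
                       "16:0" = 3, "16:1" = 3, "18:1" = 7,
                       "18:2" = 6, "18:3" = 6))
  dg_chains <- pair_unique(list(dg1, dg2))
  dg_names <- apply(dg_chains, 1, function(r)
    paste0("DG(", paste(r, collapse = "/"), ")"))
  dg <- fixture_species(dg_names, "+NH4", "positive", c("A", "B"))

  # oxidized glycerolipids: 13 TG_1OX (9 with 18:1+O, 4 with 18:2+O),
  # 11 TG_2OX (18:2+OO), 1 DG_OX (18:2+OO); six of the 25 share a chain
  # composition with a non-oxidized parent above. Chains 22:0/23:0/24:0
  # never occur in TG/DG, which keeps the remaining 19 parent-free.
  parent_with <- function(fa, k) {
    hits <- which(apply(tg_chains, 1, function(r) sum(r == fa) >= 1L))
    tg_chains[hits[seq_len(k)], , drop = FALSE]
  }
  oxidize <- function(rows, fa, suffix) {
    apply(rows, 1, function(r) {
      i <- which(r == fa)[1]
      r[i] <- paste0(fa, suffix)
      paste0("TG(", paste(r, collapse = "/"), ")")
    })
  }
  tg1ox_names <- c(
    oxidize(parent_with("18:1", 3), "18:1", "+O"),            # parent-matched
    paste0("TG(22:0/", c("14:0", "15:0", "16:0", "17:0", "4:0", "23:0"),
           "/18:1+O)"),                                        # parent-free
    oxidize(parent_with("18:2", 1), "18:2", "+O"),
    paste0("TG(23:0/", c("14:0", "15:0", "16:0"), "/18:2+O)")
  )
  tg2ox_names <- c(
    oxidize(parent_with("18:2", 2)[2, , drop = FALSE], "18:2", "+OO"),
    paste0("TG(24:0/", c("14:0", "15:0", "16:0", "17:0", "4:0", "22:0",
                         "23:0", "18:1", "18:2", "18:3"), "/18:2+OO)")
  )
  ox_adducts <- rep_len(c("+NH4", "+Na", "+H"), length(tg1ox_names) +
                          length(tg2ox_names))
  tgox <- fixture_species(c(tg1ox_names, tg2ox_names), ox_adducts,
                          "positive", c("A", "B"))
  dgox_parent <- dg_chains[which(dg_chains[, 2] == "18:2")[1], ]
  dgox <- fixture_species(
    paste0("DG(", dgox_parent[1], "/18:2+OO)"), "+NH4", "positive", "A")

  lpc <- fixture_species(
    paste0("LPC(", c("12:0", "14:0", "15:0", "16:0", "17:0", "18:1",
                     "18:2", "18:3"), ")"), "+H", "positive", c("A", "B"))
  pc_pos <- fixture_species(
    c("PC(16:0/18:1)", "PC(16:0/18:2)", "PC(18:1/18:2)"),
    "+H", "positive", c("A", "B"))
  pe <- fixture_species(
    c("PE(16:0/18:1)", "PE(16:0/18:2)", "PE(16:0/18:3)", "PE(18:1/18:1)",
      "PE(18:1/18:2)", "PE(17:0/18:1)", "PE(15:0/18:1)", "PE(14:0/18:1)"),
    "+H", "positive", c("A", "B"))
  bismepa <- fixture_species("BisMePA(16:0/18:1)", "+Na", "positive", "A")
  che <- fixture_species("ChE(18:1)", "+H-H2O", "positive", "A")

  cer <- fixture_species(
    c("Cer(d18:1/16:0)", "Cer(d18:1/22:0)", "Cer(d18:1/23:0)",
      "Cer(d18:1/24:0)", "Cer(d16:1/22:0)", "Cer(d16:1/24:0)"),
    "+HCOO", "negative", c("A", "B"))
  hex1 <- fixture_species(
    c("Hex1Cer(d18:1/16:0)", "Hex1Cer(d18:1/22:0)", "Hex1Cer(d18:1/24:0)",
      "Hex1Cer(d16:1/23:0)"), "+HCOO", "negative", c("A", "B"))
  hex2 <- fixture_species(
    c("Hex2Cer(d18:1/16:0)", "Hex2Cer(d18:1/22:0)", "Hex2Cer(d18:1/24:0)"),
    "+HCOO", "negative", c("A", "B"))
  pc_neg <- fixture_species(
    c("PC(14:0/18:1)", "PC(15:0/18:1)", "PC(16:0/18:1)", "PC(16:0/18:2)",
      "PC(17:0/18:2)", "PC(18:1/18:2)"), "+HCOO", "negative", c("A", "B"))
  sm <- fixture_species(
    c("SM(d18:1/14:0)", "SM(d18:1/16:0)", "SM(d18:1/17:0)", "SM(d16:1/22:0)",
      "SM(d16:1/23:0)", "SM(d18:1/22:0)", "SM(d18:1/23:0)", "SM(d18:1/24:0)"),
    "+HCOO", "negative", c("A", "B"))
  pi <- fixture_species(
    c("PI(16:0/18:1)", "PI(16:0/18:2)", "PI(17:0/18:1)", "PI(18:1/18:2)",
      "PI(15:0/18:1)"), "-H", "negative", c("A", "B"))
  ps <- fixture_species(
    c("PS(16:0/18:1)", "PS(16:0/18:2)", "PS(18:1/18:2)"),
    "-H", "negative", c("A", "B"))
  lpe <- fixture_species(
    c("LPE(16:0)", "LPE(18:1)", "LPE(18:2)", "LPE(12:0)"),
    "-H", "negative", c("A", "B"))
  lps <- fixture_species(c("LPS(16:0)", "LPS(18:1)"), "-H", "negative",
                         c("A", "B"))
  lpi <- fixture_species("LPI(18:1)", "-H", "negative", "A")

  all_sp <- c(tg, tgox, dg, dgox, che, bismepa, lpc, pc_pos, pe,
              cer, hex1, hex2, pc_neg, sm, pi, ps, lpe, lps, lpi)
  keys <- vapply(all_sp, species_key, character(1))
  stopifnot(!anyDuplicated(keys))
  all_sp
}
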