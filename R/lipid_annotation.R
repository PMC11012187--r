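# Expected number of fatty-acyl chains per shorthand class token.
# Sphingolipid classes count the sphingoid base as chain 1.
lipid_chain_counts <- c(
  TG = 3L, DG = 2L, ChE = 1L, BisMePA = 2L,
  PC = 2L, PE = 2L, PI = 2L, PS = 2L,
  LPC = 1L, LPE = 1L, LPI = 1L, LPS = 1L,
  SM = 2L, Cer = 2L, Hex1Cer = 2L, Hex2Cer = 2L
)

#' Subclass vocabulary of the lipid inventory
#'
#' The 19 parse-level subclasses (oxidized glycerolipids split by oxygen
#' count, hexosyl ceramides split by sugar count). At the reporting
#' level [summarize_inventory()] merges Hex1Cer and Hex2Cer into HexCer,
#' giving the 18 subclasses used as response units throughout the
#' workflow.
#'
#' @return Character vector of subclass codes.
#' @export
lipid_subclasses <- function() {
  c("TG", "TG_1OX", "TG_2OX", "DG", "DG_OX", "ChE", "BisMePA",
    "LPC", "PC", "PE", "LPE", "PI", "LPI", "PS", "LPS",
    "SM", "Cer", "Hex1Cer", "Hex2Cer")
}

parse_error <- function(class, msg, name) {
  stop(errorCondition(paste0(msg, " in '", name, "'"),
                      class = c(class, "lipid_parse_error", "error")))
}

parse_chain <- function(token, sn_index, raw_name) {
  m <- regmatches(token, regexec("^(d?)([0-9]+):([0-9]+)(\\+OO|\\+O)?$", token))[[1]]
  if (length(m) == 0L) {
    parse_error("lipid_malformed_chain", paste0("malformed chain token '", token, "'"),
                raw_name)
  }
  carbons <- as.integer(m[3])
  dbl <- as.integer(m[4])
  ox <- switch(m[5], "+O" = 1L, "+OO" = 2L, 0L)
  if (carbons < 2L) {
    parse_error("lipid_malformed_chain",
                paste0("chain '", token, "' has fewer than 2 carbons"), raw_name)
  }
  if (dbl > carbons / 2) {
    parse_error("lipid_malformed_chain",
                paste0("chain '", token, "' has more double bonds than chemically possible"),
                raw_name)
  }
  list(carbons = carbons, double_bonds = dbl, oxygens_added = ox,
       sphingoid = m[2] == "d", sn_index = sn_index)
}

#' Parse a lipid shorthand name
#'
#' Understands the grammar `Class(chain/chain/...)` (or `_`-separated),
#' with chains written `[d]C:D[+O|+OO]`: carbons:double-bonds, an
#' optional `d` prefix marking a sphingoid base and `+O`/`+OO` marking
#' one or two added oxygens. A `/` separator means the sn positions are
#' resolved; `_` means the chain order is unknown. Oxidation suffixes
#' promote the subclass: TG with one added oxygen becomes TG_1OX, with
#' two TG_2OX; DG with any becomes DG_OX.
#'
#' Errors are signalled as typed conditions: `lipid_unknown_class`,
#' `lipid_chain_count_mismatch`, `lipid_malformed_chain` (all inheriting
#' from `lipid_parse_error`).
#'
#' @param name Shorthand text, e.g. `"TG(4:0/18:1/18:2)"`.
#' @param adduct Observed adduct, e.g. `"+NH4"`, `"-H"` (optional
#'   metadata).
#' @param ion_mode `"positive"` or `"negative"`; inferred from the
#'   adduct sign when missing.
#' @param grade Identification grade letter A--D (optional).
#' @return An object of class `lipid_species`: list with `subclass`,
#'   `base_class`, `chains` (each with `carbons`, `double_bonds`,
#'   `oxygens_added`, `sphingoid`, `sn_index`), `sn_resolved`, `adduct`,
#'   `ion_mode`, `grade`, `raw_name`.
#' @examples
#' sp <- parse_lipid_name("TG(16:0/18:1/18:2+OO)")
#' sp$subclass  # "TG_2OX"
#' @export
parse_lipid_name <- function(name, adduct = NA_character_,
                             ion_mode = NA_character_,
                             grade = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  m <- regmatches(name, regexec("^([A-Za-z0-9]+)\\((.+)\\)$", name))[[1]]
  if (length(m) == 0L) {
    parse_error("lipid_malformed_chain", "name does not match Class(chains)", name)
  }
  cls <- m[2]
  if (!cls %in% names(lipid_chain_counts)) {
    parse_error("lipid_unknown_class", paste0("unknown lipid class '", cls, "'"),
                name)
  }
  body <- m[3]
  sn_resolved <- !grepl("_", body, fixed = TRUE)
  tokens <- strsplit(body, "[/_]")[[1]]
  expected <- lipid_chain_counts[[cls]]
  if (length(tokens) != expected) {
    parse_error("lipid_chain_count_mismatch",
                paste0(cls, " requires ", expected, " chain(s), found ",
                       length(tokens)), name)
  }
  chains <- lapply(seq_along(tokens), function(i) {
    parse_chain(tokens[i], if (sn_resolved) i else NA_integer_, name)
  })
  total_ox <- sum(vapply(chains, `[[`, integer(1), "oxygens_added"))
  subclass <- cls
  if (cls == "TG" && total_ox == 1L) subclass <- "TG_1OX"
  if (cls == "TG" && total_ox >= 2L) subclass <- "TG_2OX"
  if (cls == "DG" && total_ox >= 1L) subclass <- "DG_OX"

  if (is.na(ion_mode) && !is.na(adduct)) {
    ion_mode <- if (startsWith(adduct, "-")) "negative" else "positive"
  }
  structure(
    list(subclass = subclass, base_class = cls, chains = chains,
         sn_resolved = sn_resolved, adduct = adduct, ion_mode = ion_mode,
         grade = grade, raw_name = name),
    class = "lipid_species"
  )
}

format_chain <- function(ch) {
  paste0(if (ch$sphingoid) "d" else "", ch$carbons, ":", ch$double_bonds,
         c("", "+O", "+OO")[ch$oxygens_added + 1L])
}

#' Canonical shorthand of a parsed lipid species
#'
#' `format(parse_lipid_name(x))` is the canonical form of `x`:
#' resolved-position chains keep their order with `/` separators;
#' unresolved chains are sorted lexicographically and joined with `_`.
#'
#' @param x A `lipid_species`.
#' @param ... Unused.
#' @return Character scalar.
#' @export
format.lipid_species <- function(x, ...) {
  toks <- vapply(x$chains, format_chain, character(1))
  if (!x$sn_resolved) toks <- sort(toks)
  paste0(x$base_class, "(", paste(toks, collapse = if (x$sn_resolved) "/" else "_"), ")")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s] %s %s grade %s\n", format(x), x$subclass,
              x$adduct %||% NA, x$ion_mode %||% NA, x$grade %||% NA))
  invisible(x)
}

#' Classify a fatty acyl chain by saturation and chain length
#'
#' Saturation: SFA (no double bonds), MUFA (one), PUFA (two or more).
#' Chain length: short (S-C, up to 10 carbons), medium (M-C, 11--15),
#' long (L-C, `lc_min` and above). The long-chain boundary defaults to
#' 16 carbons so the three length classes partition all chains (palmitic
#' acid 16:0 counts as long-chain); it is configurable.
#'
#' @param chain A chain element of a `lipid_species`, or a list with
#'   `carbons` and `double_bonds`.
#' @param lc_min Smallest carbon count counted as long-chain.
#' @return List with `saturation` (`"SFA"`, `"MUFA"`, `"PUFA"`),
#'   `chain_length_class` (`"S-C"`, `"M-C"`, `"L-C"`), `odd_chain`.
#' @examples
#' classify_fa(list(carbons = 18, double_bonds = 2))  # PUFA, L-C
#' @export
classify_fa <- function(chain, lc_min = 16L) {
  c_n <- chain$carbons
  d <- chain$double_bonds
  list(
    saturation = if (d == 0) "SFA" else if (d == 1) "MUFA" else "PUFA",
    chain_length_class = if (c_n >= lc_min) "L-C"
                         else if (c_n >= 11) "M-C" else "S-C",
    odd_chain = c_n %% 2L == 1L
  )
}

#' Canonical species key (name + ion mode)
#' @param sp A `lipid_species`.
#' @return Character scalar identifying the species.
#' @keywords internal
#' @noRd
species_key <- function(sp) paste0(format(sp), "|", sp$ion_mode %||% NA)

# chain composition ignoring added oxygens (and order), for matching an
# oxidized species to its non-oxidized parent
deox_composition <- function(sp) {
  toks <- vapply(sp$chains, function(ch) {
    paste0(if (ch$sphingoid) "d" else "", ch$carbons, ":", ch$double_bonds)
  }, character(1))
  paste(sort(toks), collapse = "_")
}

#' Summarize a parsed lipid inventory
#'
#' Produces the descriptive statistics of an identification table:
#' species counts per subclass (hexosyl ceramides merged into HexCer at
#' this level, giving 18 subclasses when all are present), per-sn-position
#' saturation and chain-length tallies for the TG and DG families, the
#' most frequent fatty acid at each position, and cross-links between
#' oxidized species and parents sharing the same chain composition once
#' the added oxygens are ignored.
#'
#' @param species List of `lipid_species` (see [parse_lipid_name()],
#'   [read_lipid_table()]).
#' @param lc_min Long-chain boundary passed to [classify_fa()].
#' @return An object of class `subclass_summary`: list with
#'   `subclass_counts` (named vector, reporting level), `n_species`,
#'   `n_subclasses`, `tg_positions` / `dg_positions` (per-position data
#'   frames of saturation counts, chain-length percentages and the most
#'   frequent FA), `oxidized_parents` (data frame linking oxidized
#'   species to parents), `adduct_table` (counts by subclass, adduct and
#'   ion mode).
#' @export
summarize_inventory <- function(species, lc_min = 16L) {
  if (length(species) == 0L) {
    return(structure(list(subclass_counts = integer(0), n_species = 0L,
                          n_subclasses = 0L, tg_positions = NULL,
                          dg_positions = NULL, oxidized_parents = NULL,
                          adduct_table = NULL),
                     class = "subclass_summary"))
  }
  lapply(species, function(s) stopifnot(inherits(s, "lipid_species")))
  sub <- vapply(species, `[[`, character(1), "subclass")
  report_sub <- ifelse(sub %in% c("Hex1Cer", "Hex2Cer"), "HexCer", sub)
  counts <- table(report_sub)
  counts <- stats::setNames(as.integer(counts), names(counts))

  position_tally <- function(fam_classes, n_pos) {
    idx <- sub %in% fam_classes
    if (!any(idx)) return(NULL)
    fam <- species[idx]
    do.call(rbind, lapply(seq_len(n_pos), function(pos) {
      chains <- lapply(fam, function(s) s$chains[[pos]])
      ann <- lapply(chains, classify_fa, lc_min = lc_min)
      satur <- vapply(ann, `[[`, character(1), "saturation")
      len <- vapply(ann, `[[`, character(1), "chain_length_class")
      fa <- vapply(chains, format_chain, character(1))
      fa_tab <- sort(table(fa), decreasing = TRUE)
      data.frame(
        position = paste0("sn-", pos), n = length(chains),
        SFA = sum(satur == "SFA"), MUFA = sum(satur == "MUFA"),
        PUFA = sum(satur == "PUFA"),
        pct_SC = 100 * mean(len == "S-C"), pct_MC = 100 * mean(len == "M-C"),
        pct_LC = 100 * mean(len == "L-C"),
        most_frequent_fa = names(fa_tab)[1],
        most_frequent_fa_n = as.integer(fa_tab[1]),
        stringsAsFactors = FALSE
      )
    }))
  }

  keys <- vapply(species, species_key, character(1))
  is_ox <- sub %in% c("TG_1OX", "TG_2OX", "DG_OX")
  parents_comp <- vapply(species[!is_ox], deox_composition, character(1))
  ox_links <- NULL
  if (any(is_ox)) {
    ox_links <- do.call(rbind, lapply(which(is_ox), function(i) {
      comp <- deox_composition(species[[i]])
      hits <- which(parents_comp == comp)
      data.frame(oxidized = keys[i],
                 parent = if (length(hits)) keys[!is_ox][hits[1]] else NA_character_,
                 has_parent = length(hits) > 0L, stringsAsFactors = FALSE)
    }))
  }

  adduct_table <- as.data.frame(table(
    subclass = sub,
    adduct = vapply(species, function(s) s$adduct %||% NA_character_, character(1)),
    ion_mode = vapply(species, function(s) s$ion_mode %||% NA_character_, character(1))
  ), stringsAsFactors = FALSE)
  adduct_table <- adduct_table[adduct_table$Freq > 0, , drop = FALSE]
  rownames(adduct_table) <- NULL

  structure(
    list(subclass_counts = counts, n_species = length(species),
         n_subclasses = length(counts),
         tg_positions = position_tally("TG", 3L),
         dg_positions = position_tally("DG", 2L),
         oxidized_parents = ox_links, adduct_table = adduct_table),
    class = "subclass_summary"
  )
}

#' @export
print.subclass_summary <- function(x, ...) {
  cat("<subclass_summary>", x$n_species, "species in", x$n_subclasses,
      "subclasses\n")
  if (x$n_species > 0) print(x$subclass_counts)
  invisible(x)
}

#' Compare two lipid inventories per subclass
#'
#' Species identity is the canonical name plus ion mode, so the same
#' molecule observed in both modes counts twice, mirroring how
#' identification software reports it.
#'
#' @param table_a,table_b Lists of `lipid_species` (e.g. the MAE and
#'   Folch extractions of the same sample).
#' @param labels Length-2 character vector naming the two methods.
#' @return An object of class `method_comparison`: list with `counts`
#'   (data frame subclass, count_a, count_b, shared, unique_a, unique_b)
#'   and `species` (per-subclass list of shared/unique canonical names).
#' @export
compare_methods <- function(table_a, table_b, labels = c("a", "b")) {
  key_sub <- function(tab) {
    if (length(tab) == 0L) return(data.frame(key = character(0),
                                             subclass = character(0)))
    data.frame(key = vapply(tab, species_key, character(1)),
               subclass = vapply(tab, `[[`, character(1), "subclass"),
               stringsAsFactors = FALSE)
  }
  a <- key_sub(table_a); b <- key_sub(table_b)
  subs <- sort(union(a$subclass, b$subclass))
  species <- stats::setNames(vector("list", length(subs)), subs)
  counts <- do.call(rbind, lapply(subs, function(s) {
    ka <- a$key[a$subclass == s]; kb <- b$key[b$subclass == s]
    species[[s]] <<- list(shared = intersect(ka, kb),
                          unique_a = setdiff(ka, kb),
                          unique_b = setdiff(kb, ka))
    data.frame(subclass = s, count_a = length(ka), count_b = length(kb),
               shared = length(intersect(ka, kb)),
               unique_a = length(setdiff(ka, kb)),
               unique_b = length(setdiff(kb, ka)), stringsAsFactors = FALSE)
  }))
  structure(list(counts = counts, species = species, labels = labels),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>", x$labels[1], "vs", x$labels[2], "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' QC gate on replicate peak areas of internal standards
#'
#' Computes the relative standard deviation (RSD% = 100 sd/mean) of the
#' replicate peak areas of each deuterated standard and flags standards
#' whose RSD% is strictly below the threshold as passing; an RSD exactly
#' at the threshold fails. A zero mean makes the RSD undefined and fails
#' with a reason.
#'
#' @param areas Named list (or data frame) of numeric replicate peak
#'   areas, one element per standard, each with at least 2 replicates.
#' @param threshold_pct Pass threshold in percent (default 20).
#' @return An object of class `qc_report`: data frame with columns
#'   `standard`, `n`, `mean`, `sd`, `rsd_pct`, `pass`, `reason`;
#'   attribute `"threshold_pct"`.
#' @examples
#' qc_check(list(d7_PC = c(100, 102, 98)))
#' @export
qc_check <- function(areas, threshold_pct = 20) {
  areas <- as.list(areas)
  if (is.null(names(areas)) || any(!nzchar(names(areas)))) {
    names(areas) <- paste0("standard", seq_along(areas))
  }
  rows <- lapply(names(areas), function(nm) {
    x <- as.numeric(areas[[nm]])
    if (length(x) < 2L) {
      stop("standard '", nm, "' needs at least 2 replicates", call. = FALSE)
    }
    m <- mean(x); s <- stats::sd(x)
    if (m == 0) {
      return(data.frame(standard = nm, n = length(x), mean = m, sd = s,
                        rsd_pct = NA_real_, pass = FALSE,
                        reason = "zero mean: RSD undefined",
                        stringsAsFactors = FALSE))
    }
    rsd <- 100 * s / abs(m)
    data.frame(standard = nm, n = length(x), mean = m, sd = s, rsd_pct = rsd,
               pass = rsd < threshold_pct,
               reason = if (rsd < threshold_pct) "" else
                 sprintf("RSD %.1f%% >= %.1f%%", rsd, threshold_pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold_pct") <- threshold_pct
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Read a lipid identification export
#'
#' Reads a delimited identification table with columns `LipidName`,
#' `Adduct`, `IonMode`, `Grade` and `Area` (extra columns are kept but
#' ignored; missing metadata columns become `NA`). Each name is parsed
#' with [parse_lipid_name()]; unparseable rows are collected with their
#' line numbers rather than aborting the read.
#'
#' @param path File path (tab- or comma-separated, autodetected from the
#'   extension: `.csv` means comma).
#' @param grades Optional character vector: keep only these
#'   identification grades (e.g. `c("A", "B")`).
#' @return List with `species` (list of `lipid_species`), `table` (the
#'   raw data frame of parsed rows), `failures` (data frame line/name/
#'   error for rows that did not parse).
#' @export
read_lipid_table <- function(path, grades = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"LipidName" %in% names(df)) {
    stop("identification table must have a LipidName column", call. = FALSE)
  }
  for (col in c("Adduct", "IonMode", "Grade", "Area")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (!is.null(grades)) df <- df[df$Grade %in% grades, , drop = FALSE]
  species <- vector("list", nrow(df))
  ok <- logical(nrow(df))
  failures <- NULL
  for (i in seq_len(nrow(df))) {
    sp <- tryCatch(
      parse_lipid_name(df$LipidName[i], adduct = df$Adduct[i],
                       ion_mode = df$IonMode[i], grade = df$Grade[i]),
      lipid_parse_error = function(e) e
    )
    if (inherits(sp, "lipid_species")) {
      species[[i]] <- sp; ok[i] <- TRUE
    } else {
      failures <- rbind(failures,
                        data.frame(line = i + 1L, name = df$LipidName[i],
                                   error = conditionMessage(sp),
                                   stringsAsFactors = FALSE))
    }
  }
  list(species = species[ok], table = df[ok, , drop = FALSE],
       failures = failures)
}

#' Write a lipid identification table
#'
#' @param species List of `lipid_species`.
#' @param path Output path (tab-separated; `.csv` writes commas).
#' @param areas Optional numeric vector of peak areas.
#' @return Invisibly, `path`.
#' @export
write_lipid_table <- function(species, path, areas = NULL) {
  df <- data.frame(
    LipidName = vapply(species, function(s) s$raw_name, character(1)),
    Adduct = vapply(species, function(s) s$adduct %||% NA_character_, character(1)),
    IonMode = vapply(species, function(s) s$ion_mode %||% NA_character_, character(1)),
    Grade = vapply(species, function(s) s$grade %||% NA_character_, character(1)),
    Area = if (is.null(areas)) NA_real_ else areas,
    stringsAsFactors = FALSE
  )
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
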