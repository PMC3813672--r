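# Molar-oxide weathering indices computed from elemental totals.
#
# Convention: the mole amount of an oxide per 100 g soil is the element mass
# fraction divided by its atomic mass, halved for R2O/R2O3 oxides (two
# cations per formula unit). Total K is reported in g/kg and is divided by
# 10 to a mass percent before entering any index.

.atomic_mass <- c(na = 22.99, mg = 24.31, al = 26.98, si = 28.09,
                  k = 39.10, ca = 40.08, fe = 55.85)
.oxide_stoich <- c(na = 2, mg = 1, al = 2, si = 1, k = 2, ca = 1, fe = 2)

#' Oxide-mole conversion table
#'
#' The fixed constants behind the weathering indices: atomic masses (g/mol)
#' and cations per oxide formula unit (Na2O, MgO, Al2O3, SiO2, K2O, CaO,
#' Fe2O3).
#'
#' @return data frame with columns `element`, `atomic_mass`,
#'   `oxide_stoichiometry`.
#' @export
oxide_basis <- function() {
  data.frame(element = names(.atomic_mass),
             atomic_mass = unname(.atomic_mass),
             oxide_stoichiometry = unname(.oxide_stoich[names(.atomic_mass)]))
}

.ox_moles <- function(element, mass_pct) {
  mass_pct / .atomic_mass[[element]] / .oxide_stoich[[element]]
}

#' Sodium/potassium mass-fraction ratio
#'
#' @param na_pct total Na, mass %.
#' @param k_gkg total K, g/kg (converted to % internally).
#' @return Na%/K% (unitless).
#' @examples
#' na_k_ratio(0.44, 14.93)  # 0.29 at 2-dp
#' @export
na_k_ratio <- function(na_pct, k_gkg) {
  if (any(k_gkg <= 0)) stop("domain error: k_gkg must be > 0", call. = FALSE)
  na_pct / (k_gkg / 10)
}

#' Chemical index of alteration (CIA)
#'
#' Molar `100 * Al2O3 / (Al2O3 + CaO + Na2O + K2O)`. CaO is the total-Ca
#' oxide without silicate correction, which is the convention that
#' reproduces the packaged survey's printed index column most closely
#' (see the methods vignette for the residual sensitivity of CIA to the
#' 2-dp rounding of the printed inputs).
#'
#' @param al_pct,ca_pct,na_pct mass % of Al, Ca, Na.
#' @param k_gkg total K in g/kg.
#' @return CIA in (0, 100].
#' @export
cia <- function(al_pct, ca_pct, na_pct, k_gkg) {
  if (any(c(al_pct, ca_pct, na_pct, k_gkg) < 0))
    stop("domain error: negative input", call. = FALSE)
  al <- .ox_moles("al", al_pct)
  den <- al + .ox_moles("ca", ca_pct) + .ox_moles("na", na_pct) +
    .ox_moles("k", k_gkg / 10)
  if (any(den == 0)) stop("domain error: all-zero input", call. = FALSE)
  100 * al / den
}

#' Silica/sesquioxide ratio (saf)
#'
#' Molar `SiO2 / (Al2O3 + Fe2O3)`, a leaching-intensity index.
#'
#' @param si_pct,al_pct,fe_pct mass % of Si, Al, Fe.
#' @return saf (unitless, >= 0).
#' @export
saf <- function(si_pct, al_pct, fe_pct) {
  den <- .ox_moles("al", al_pct) + .ox_moles("fe", fe_pct)
  if (any(den == 0)) stop("domain error: Al + Fe must be > 0", call. = FALSE)
  .ox_moles("si", si_pct) / den
}

#' Base/alumina ratio (ba)
#'
#' Molar `(CaO + MgO + Na2O + K2O) / Al2O3`; decreases with weathering.
#' Mg is the first Mg column of the survey layout (the second, larger Mg
#' column does not reproduce the printed index and is carried as data only).
#'
#' @param ca_pct,mg_pct,na_pct,al_pct mass %.
#' @param k_gkg total K in g/kg.
#' @return ba (unitless, >= 0).
#' @export
ba <- function(ca_pct, mg_pct, na_pct, k_gkg, al_pct) {
  if (any(al_pct <= 0)) stop("domain error: al_pct must be > 0", call. = FALSE)
  (.ox_moles("ca", ca_pct) + .ox_moles("mg", mg_pct) +
     .ox_moles("na", na_pct) + .ox_moles("k", k_gkg / 10)) / .ox_moles("al", al_pct)
}

#' Compute all four weathering indices for a survey table
#'
#' Derives `na_k`, `cia`, `saf` and `ba` from the elemental totals of a
#' [sample_table()]. The ICA column, whose defining formula is not
#' recoverable, is never computed: printed ICA values pass through untouched.
#'
#' @param table a [sample_table()] with columns `na`, `mg_a`, `al`, `si`,
#'   `fe`, `ca`, `k`.
#' @param compare if `TRUE` and the table already carries index columns,
#'   return a per-row deviation report instead of the augmented table.
#' @return the table with index columns appended/overwritten, or (with
#'   `compare = TRUE`) a data frame of computed vs present values and their
#'   difference at 2-dp rounding.
#' @examples
#' tab <- load_fixture("survey")
#' head(compute_indices(tab, compare = TRUE))
#' @export
compute_indices <- function(table, compare = FALSE) {
  need <- c("na", "mg_a", "al", "si", "fe", "ca", "k")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("schema error: missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  message("unit conversion: total K g/kg -> mass % (divide by 10)")
  comp <- data.frame(
    group = table$group,
    na_k = na_k_ratio(table$na, table$k),
    cia = cia(table$al, table$ca, table$na, table$k),
    saf = saf(table$si, table$al, table$fe),
    ba = ba(table$ca, table$mg_a, table$na, table$k, table$al))
  if (compare) {
    have <- intersect(c("na_k", "cia", "saf", "ba"), names(table))
    rep <- data.frame(group = rep(table$group, length(have)),
                      index = rep(have, each = nrow(table)))
    rep$computed <- unlist(lapply(have, function(i) round(comp[[i]], 2)))
    rep$printed <- unlist(lapply(have, function(i) table[[i]]))
    rep$deviation <- rep$computed - rep$printed
    return(rep)
  }
  for (i in c("na_k", "cia", "saf", "ba")) table[[i]] <- comp[[i]]
  table
}
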