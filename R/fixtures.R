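# Small, fully specified mass-action fixture networks with known analytic
# structure. The motifs echo the biology of receptor-driven signaling: a
# ligand/receptor dimerization block inhibited by an antibody-like drug, and
# two phosphorylation cascades coupled through a shared phosphatase (the
# PP2A-style crosstalk mechanism). Kinetics are generic mass action with
# constants of order 0.01-1 (nM, min units); they are stand-ins with the
# right qualitative structure, not a published parameterization.

FIXTURE_MOTIFS <- c("decay", "reversible_pair", "linear_cascade",
                    "receptor_inhibitor", "crosstalk_shared_phosphatase")

#' Generate a fixture network with documented analytic properties
#'
#' Motifs:
#' \describe{
#'   \item{decay}{`A -> B`, `v = k A`; closed form `A(t) = A0 exp(-k t)`;
#'     `A + B` conserved. Defaults `k = 0.1`/min, `A0 = 10` nM.}
#'   \item{reversible_pair}{`A <-> B` as two mass-action reactions;
#'     `A + B` conserved.}
#'   \item{linear_cascade}{`n` tiers of inactive/active pairs; tier 1
#'     activates constitutively, tier i is activated by the active form of
#'     tier i-1 (as modifier); each tier's total is conserved.}
#'   \item{receptor_inhibitor}{`L + R3 <-> LR3`; `LR3 + R2 <-> D` (active
#'     dimer); `I + R2 <-> IR2` — a ligand/receptor dimerization block with
#'     an antibody-like inhibitor sequestering the co-receptor. Receptor,
#'     ligand and inhibitor totals are conserved.}
#'   \item{crosstalk_shared_phosphatase}{cascades `X -> Xa` and `Y -> Ya`
#'     both dephosphorylated by a shared, limiting phosphatase `P` via
#'     complexes `XaP`, `YaP`; a drug `I` sequesters inactive `X`
#'     (`I + X <-> IX`), so inhibiting the X cascade frees `P` and raises
#'     the `YaP` complex on the other cascade.}
#' }
#'
#' @param motif One of `decay`, `reversible_pair`, `linear_cascade`,
#'   `receptor_inhibitor`, `crosstalk_shared_phosphatase`.
#' @param n Number of cascade tiers (linear_cascade only), >= 1.
#' @param rates Named numeric overrides of the motif's rate constants.
#' @param init Named numeric overrides of initial concentrations (nM).
#' @param jitter If `TRUE`, multiply every rate constant by a seeded
#'   log-normal factor (sd 0.2); off by default.
#' @param seed Seed for the jitter draw.
#' @return A list of class `"fixture"`: `network`, `motif`, `notes`
#'   (character vector of analytic properties) and `conserved` (named list;
#'   each element a named weight vector over species whose weighted sum is
#'   constant in simulation).
#' @export
make_fixture <- function(motif = FIXTURE_MOTIFS, n = 3, rates = NULL,
                         init = NULL, jitter = FALSE, seed = 1L) {
  motif <- match.arg(motif)
  if (motif == "linear_cascade" && (!is.numeric(n) || n < 1))
    stop("linear_cascade needs n >= 1 tiers", call. = FALSE)
  fx <- switch(motif,
    decay = motif_decay(),
    reversible_pair = motif_reversible_pair(),
    linear_cascade = motif_cascade(as.integer(n)),
    receptor_inhibitor = motif_receptor_inhibitor(),
    crosstalk_shared_phosphatase = motif_crosstalk())
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(fx$params))
    if (length(bad)) stop("unknown rate constant(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(rates <= 0)) stop("rate constants must be > 0", call. = FALSE)
    fx$params[names(rates)] <- rates
  }
  if (!is.null(init)) {
    bad <- setdiff(names(init), fx$species$id)
    if (length(bad)) stop("unknown species in init: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(init < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
    fx$species$initial_concentration[match(names(init), fx$species$id)] <- init
  }
  if (isTRUE(jitter))
    fx$params <- fx$params *
      with_seed(seed, exp(stats::rnorm(length(fx$params), 0, 0.2)))
  net <- reaction_network(fx$species, fx$reactions, fx$params,
                          id = paste0("fixture_", motif))
  structure(list(network = net, motif = motif, notes = fx$notes,
                 conserved = fx$conserved),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture> motif '", x$motif, "'\n", sep = "")
  print(x$network)
  for (nt in x$notes) cat("  - ", nt, "\n", sep = "")
  invisible(x)
}

motif_decay <- function() {
  list(
    species = rbind(species("A", initial_concentration = 10),
                    species("B", initial_concentration = 0)),
    reactions = list(reaction("deg", c(A = 1), c(B = 1),
                              kinetic_law = quote(k * A))),
    params = c(k = 0.1),
    notes = c("closed form: A(t) = A0 * exp(-k t), B(t) = A0 - A(t)",
              "conserved: A + B"),
    conserved = list(total = c(A = 1, B = 1)))
}

motif_reversible_pair <- function() {
  list(
    species = rbind(species("A", initial_concentration = 8),
                    species("B", initial_concentration = 2)),
    reactions = list(
      reaction("fwd", c(A = 1), c(B = 1), kinetic_law = quote(kf * A)),
      reaction("rev", c(B = 1), c(A = 1), kinetic_law = quote(kr * B))),
    params = c(kf = 0.3, kr = 0.2),
    notes = c("relaxes to equilibrium B/A = kf/kr", "conserved: A + B"),
    conserved = list(total = c(A = 1, B = 1)))
}

motif_cascade <- function(n) {
  sp <- list(); rx <- list(); params <- numeric(); cons <- list()
  for (i in seq_len(n)) {
    xi <- paste0("X", i); xa <- paste0("X", i, "a")
    sp[[length(sp) + 1L]] <- species(xi, initial_concentration = 10)
    sp[[length(sp) + 1L]] <- species(xa, initial_concentration = 0)
    kact <- paste0("k_act", i); kde <- paste0("k_deact", i)
    if (i == 1L) {
      law <- bquote(.(as.name(kact)) * .(as.name(xi)))
      params[kact] <- 0.5
      rx[[length(rx) + 1L]] <- reaction(paste0("act", i), stats::setNames(1, xi),
                                        stats::setNames(1, xa),
                                        kinetic_law = law)
    } else {
      up <- paste0("X", i - 1, "a")
      law <- bquote(.(as.name(kact)) * .(as.name(xi)) * .(as.name(up)))
      params[kact] <- 0.1
      rx[[length(rx) + 1L]] <- reaction(paste0("act", i), stats::setNames(1, xi),
                                        stats::setNames(1, xa),
                                        modifiers = up, kinetic_law = law)
    }
    params[kde] <- 0.2
    rx[[length(rx) + 1L]] <- reaction(paste0("deact", i),
                                      stats::setNames(1, xa),
                                      stats::setNames(1, xi),
                                      kinetic_law = bquote(.(as.name(kde)) * .(as.name(xa))))
    cons[[paste0("tier", i)]] <- stats::setNames(c(1, 1), c(xi, xa))
  }
  list(species = do.call(rbind, sp), reactions = rx, params = params,
       notes = c(paste0(n, "-tier activation cascade; each tier's total is conserved"),
                 "tier 1 activates constitutively; tier i is catalyzed by tier i-1's active form"),
       conserved = cons)
}

motif_receptor_inhibitor <- function() {
  list(
    species = rbind(
      species("L", initial_concentration = 10),
      species("R3", initial_concentration = 10),
      species("LR3", initial_concentration = 0),
      species("R2", initial_concentration = 10),
      species("D", initial_concentration = 0),
      species("I", initial_concentration = 0),
      species("IR2", initial_concentration = 0)),
    reactions = list(
      reaction("bind_L", c(L = 1, R3 = 1), c(LR3 = 1),
               kinetic_law = quote(kon1 * L * R3)),
      reaction("unbind_L", c(LR3 = 1), c(L = 1, R3 = 1),
               kinetic_law = quote(koff1 * LR3)),
      reaction("dimerize", c(LR3 = 1, R2 = 1), c(D = 1),
               kinetic_law = quote(kdim * LR3 * R2)),
      reaction("undimerize", c(D = 1), c(LR3 = 1, R2 = 1),
               kinetic_law = quote(kundim * D)),
      reaction("bind_I", c(I = 1, R2 = 1), c(IR2 = 1),
               kinetic_law = quote(kon2 * I * R2)),
      reaction("unbind_I", c(IR2 = 1), c(I = 1, R2 = 1),
               kinetic_law = quote(koff2 * IR2))),
    params = c(kon1 = 0.05, koff1 = 0.1, kdim = 0.05, kundim = 0.1,
               kon2 = 0.1, koff2 = 0.01),
    notes = c("D is the active ligand-bound receptor dimer",
              "inhibitor I sequesters co-receptor R2, lowering D dose-dependently",
              "conserved: R2 + D + IR2; R3 + LR3 + D; L + LR3 + D; I + IR2"),
    conserved = list(
      co_receptor = c(R2 = 1, D = 1, IR2 = 1),
      receptor = c(R3 = 1, LR3 = 1, D = 1),
      ligand = c(L = 1, LR3 = 1, D = 1),
      inhibitor = c(I = 1, IR2 = 1)))
}

motif_crosstalk <- function() {
  list(
    species = rbind(
      species("X", initial_concentration = 10),
      species("Xa", initial_concentration = 0),
      species("Y", initial_concentration = 10),
      species("Ya", initial_concentration = 0),
      species("P", initial_concentration = 4),
      species("XaP", initial_concentration = 0),
      species("YaP", initial_concentration = 0),
      species("I", initial_concentration = 0),
      species("IX", initial_concentration = 0)),
    reactions = list(
      reaction("act_X", c(X = 1), c(Xa = 1), kinetic_law = quote(kax * X)),
      reaction("act_Y", c(Y = 1), c(Ya = 1), kinetic_law = quote(kay * Y)),
      reaction("bind_XP", c(Xa = 1, P = 1), c(XaP = 1),
               kinetic_law = quote(kbx * Xa * P)),
      reaction("release_XP", c(XaP = 1), c(X = 1, P = 1),
               kinetic_law = quote(krx * XaP)),
      reaction("bind_YP", c(Ya = 1, P = 1), c(YaP = 1),
               kinetic_law = quote(kby * Ya * P)),
      reaction("release_YP", c(YaP = 1), c(Y = 1, P = 1),
               kinetic_law = quote(kry * YaP)),
      reaction("bind_I", c(I = 1, X = 1), c(IX = 1),
               kinetic_law = quote(kbi * I * X)),
      reaction("unbind_I", c(IX = 1), c(I = 1, X = 1),
               kinetic_law = quote(kui * IX))),
    params = c(kax = 0.5, kay = 0.5, kbx = 0.2, krx = 0.1, kby = 0.2,
               kry = 0.1, kbi = 0.5, kui = 0.01),
    notes = c("shared limiting phosphatase P couples the X and Y cascades",
              "inhibiting the X cascade (dose of I) frees P and raises the YaP complex",
              "conserved: X + Xa + XaP + IX; Y + Ya + YaP; P + XaP + YaP; I + IX"),
    conserved = list(
      x_total = c(X = 1, Xa = 1, XaP = 1, IX = 1),
      y_total = c(Y = 1, Ya = 1, YaP = 1),
      phosphatase = c(P = 1, XaP = 1, YaP = 1),
      inhibitor = c(I = 1, IX = 1)))
}

#' In-memory drug catalogue for a fixture's inhibitor
#'
#' @param fix A [make_fixture()] result whose motif carries an inhibitor
#'   species `I` (receptor_inhibitor or crosstalk_shared_phosphatase).
#' @param name Drug name; default `"inhibitor"`.
#' @param dosage Default dosage, nM.
#' @return A `drug_catalogue` data frame.
#' @export
fixture_catalogue <- function(fix, name = "inhibitor", dosage = 30) {
  stopifnot(inherits(fix, "fixture"))
  if (!"I" %in% fix$network$species$id)
    stop("motif '", fix$motif, "' has no inhibitor species", call. = FALSE)
  out <- data.frame(name = name, dosage_nM = dosage, target = "I",
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_catalogue", "data.frame")
  out
}

#' Standard regime suite for a fixture
#'
#' Returns the four study regimes: untreated Control; a 30 nM inhibitor
#' bolus at t = 0; a mutation halving a motif-specific species at t = 0
#' (the 50%-reduction pattern of a resistance mutation: the shared
#' phosphatase `P` for the crosstalk motif, receptor `R3` for the
#' receptor/inhibitor motif); and the combination of both.
#'
#' @param fix A fixture with motif `receptor_inhibitor` or
#'   `crosstalk_shared_phosphatase`.
#' @param dose nM of inhibitor, default 30.
#' @param mutation_factor Scale factor of the mutation, default 0.5.
#' @return Named list of four [regime()]s: `control`, `inhibitor`,
#'   `mutation`, `combination`.
#' @export
make_regime_suite <- function(fix, dose = 30, mutation_factor = 0.5) {
  stopifnot(inherits(fix, "fixture"))
  if (!fix$motif %in% c("receptor_inhibitor", "crosstalk_shared_phosphatase"))
    stop("regime suite is defined for receptor_inhibitor and ",
         "crosstalk_shared_phosphatase motifs only", call. = FALSE)
  mut_target <- if (fix$motif == "receptor_inhibitor") "R3" else "P"
  dose_iv <- intervention("dose", "I", dose, 0)
  mut_iv <- intervention("scale_concentration", mut_target, mutation_factor, 0)
  list(control = regime("Control"),
       inhibitor = regime("Inhibitor", list(dose_iv)),
       mutation = regime("Mutation", list(mut_iv)),
       combination = regime("Combination", list(dose_iv, mut_iv)))
}

#' Write a regime as a YAML specification file
#' @param rg A [regime()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regime <- function(rg, path) {
  stopifnot(inherits(rg, "regime"))
  yaml::write_yaml(
    list(label = rg$label,
         interventions = lapply(rg$interventions, function(iv)
           list(kind = iv$kind, target = iv$target, value = iv$value,
                time = iv$time))),
    path)
  invisible(path)
}

#' Emit the full fixture tree to a directory
#'
#' One subdirectory per motif, each with the SBML model (`model.xml`), the
#' regime suite as YAML files where defined, a drug catalogue for inhibitor
#' motifs, and a top-level `manifest.json` listing every file and each
#' fixture's analytic properties.
#'
#' @param out_dir Output directory (created if absent).
#' @param cascade_n Tiers for the cascade motif.
#' @return The manifest path, invisibly.
#' @export
write_fixture_tree <- function(out_dir, cascade_n = 3) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", out_dir, call. = FALSE)
  manifest <- list()
  for (m in FIXTURE_MOTIFS) {
    fix <- make_fixture(m, n = cascade_n)
    dir <- file.path(out_dir, m)
    dir.create(dir, showWarnings = FALSE)
    files <- character()
    mp <- file.path(dir, "model.xml")
    write_sbml(fix$network, mp)
    files <- c(files, "model.xml")
    if (m %in% c("receptor_inhibitor", "crosstalk_shared_phosphatase")) {
      for (rg in make_regime_suite(fix)) {
        rp <- file.path(dir, paste0("regime_", tolower(rg$label), ".yaml"))
        write_regime(rg, rp)
        files <- c(files, basename(rp))
      }
      cp <- file.path(dir, "catalogue.csv")
      utils::write.csv(as.data.frame(fixture_catalogue(fix)), cp,
                       row.names = FALSE, quote = FALSE)
      files <- c(files, "catalogue.csv")
    }
    manifest[[m]] <- list(files = as.list(files), notes = as.list(fix$notes),
                          conserved = lapply(fix$conserved, as.list))
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
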