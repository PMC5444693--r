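INTERVENTION_KINDS <- c("dose", "set_concentration", "scale_concentration",
                        "set_parameter", "scale_parameter")

#' Create a timed intervention
#'
#' An intervention is a discontinuity applied to the model state during
#' simulation: a drug bolus (`dose` adds `value` nM to the target species), a
#' concentration override or scaling (the paper's mutation pattern, e.g. a
#' 50% reduction is `scale_concentration` with factor 0.5), or the analogous
#' operations on a kinetic constant.
#'
#' @param kind One of `dose`, `set_concentration`, `scale_concentration`,
#'   `set_parameter`, `scale_parameter`.
#' @param target Species id (concentration kinds) or parameter id
#'   (parameter kinds).
#' @param value nM for `dose`/`set_concentration`; dimensionless factor for
#'   the scale kinds; parameter units for `set_parameter`.
#' @param time Application time in minutes (>= 0).
#' @return An object of class `"intervention"`.
#' @export
intervention <- function(kind, target, value, time = 0) {
  kind <- match.arg(kind, INTERVENTION_KINDS)
  stopifnot(is.character(target), length(target) == 1L)
  if (!is.finite(value))
    stop("intervention value must be finite", call. = FALSE)
  if (!is.finite(time) || time < 0)
    stop("intervention time must be >= 0 minutes", call. = FALSE)
  if (kind %in% c("dose", "set_concentration") && value < 0)
    stop(kind, " value must be a non-negative concentration (nM)", call. = FALSE)
  if (grepl("^scale", kind) && value < 0)
    stop("scale factor must be >= 0", call. = FALSE)
  structure(list(kind = kind, target = target, value = as.numeric(value),
                 time = as.numeric(time)),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention> %s(%s, %g) @ t=%g min\n",
              x$kind, x$target, x$value, x$time))
  invisible(x)
}

#' Create a named intervention regime
#'
#' A regime is an ordered list of timed interventions; the comparison module
#' designates one regime "Control" and the other "Experiment". The empty
#' regime is the untreated control.
#'
#' @param label Regime label.
#' @param interventions List of [intervention()] objects.
#' @return An object of class `"regime"`; interventions sorted by time with
#'   ties kept in declared order.
#' @export
regime <- function(label = "Control", interventions = list()) {
  if (inherits(interventions, "intervention"))
    interventions <- list(interventions)
  stopifnot(all(vapply(interventions, inherits, TRUE, "intervention")))
  if (length(interventions)) {
    times <- vapply(interventions, `[[`, 0, "time")
    interventions <- interventions[order(times)]  # stable for ties
  }
  structure(list(label = label, interventions = interventions),
            class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  cat("<regime> '", x$label, "' with ", length(x$interventions),
      " intervention(s)\n", sep = "")
  for (iv in x$interventions)
    cat(sprintf("  t=%g min: %s(%s, %g)\n", iv$time, iv$kind, iv$target,
                iv$value))
  invisible(x)
}

#' Build a dose intervention from a drug catalogue
#'
#' Looks the drug up by name and returns a bolus targeting the catalogue's
#' bound species; when `dosage` is omitted the catalogue's default is used.
#'
#' @param catalogue A `drug_catalogue` from [load_drug_catalogue()].
#' @param drug Drug name.
#' @param dosage Dose in nM; default `NULL` uses the catalogue entry.
#' @param time Application time, minutes.
#' @return An [intervention()] of kind `dose`.
#' @export
make_dose <- function(catalogue, drug, dosage = NULL, time = 0) {
  stopifnot(inherits(catalogue, "drug_catalogue"))
  i <- match(drug, catalogue$name)
  if (is.na(i))
    stop("unknown drug '", drug, "' (catalogue has: ",
         paste(catalogue$name, collapse = ", "), ")", call. = FALSE)
  if (is.null(dosage)) dosage <- catalogue$dosage_nM[i]
  if (!is.finite(dosage) || dosage < 0)
    stop("dosage must be a non-negative concentration (nM)", call. = FALSE)
  intervention("dose", catalogue$target[i], dosage, time)
}

#' Apply one intervention to a simulation state
#'
#' Pure state transformation used by the simulator at intervention times:
#' exactly one entry of `(conc, params)` changes.
#'
#' @param conc Named numeric vector of species concentrations (nM).
#' @param params Named numeric vector of parameter values.
#' @param iv An [intervention()].
#' @return `list(conc = ..., params = ...)` with the change applied.
#' @export
apply_intervention <- function(conc, params, iv) {
  stopifnot(inherits(iv, "intervention"))
  if (iv$kind %in% c("dose", "set_concentration", "scale_concentration")) {
    if (!iv$target %in% names(conc))
      stop("intervention targets unknown species '", iv$target, "'",
           call. = FALSE)
    x <- conc[[iv$target]]
    x <- switch(iv$kind,
                dose = x + iv$value,
                set_concentration = iv$value,
                scale_concentration = x * iv$value)
    if (x < 0) {
      warning("intervention on '", iv$target,
              "' produced a negative concentration; clipped to 0")
      x <- 0
    }
    conc[[iv$target]] <- x
  } else {
    if (!iv$target %in% names(params))
      stop("intervention targets unknown parameter '", iv$target, "'",
           call. = FALSE)
    params[[iv$target]] <- switch(iv$kind,
                                  set_parameter = iv$value,
                                  scale_parameter = params[[iv$target]] * iv$value)
  }
  list(conc = conc, params = params)
}

#' Validate a regime against a network and simulation horizon
#'
#' Checks every intervention's target against the network (species for
#' concentration kinds, parameters for parameter kinds) and rejects
#' interventions scheduled after `t_end`. Returns the regime sorted by time
#' (stable for ties).
#'
#' @param rg A [regime()].
#' @param net A [reaction_network()].
#' @param t_end Simulation horizon in minutes.
#' @return The validated, sorted regime.
#' @export
validate_regime <- function(rg, net, t_end = Inf) {
  stopifnot(inherits(rg, "regime"), inherits(net, "reaction_network"))
  for (iv in rg$interventions) {
    conc_kind <- iv$kind %in% c("dose", "set_concentration", "scale_concentration")
    pool <- if (conc_kind) net$species$id else names(net$parameters)
    what <- if (conc_kind) "species" else "parameter"
    if (!iv$target %in% pool)
      stop("regime '", rg$label, "': intervention targets unknown ", what,
           " '", iv$target, "'", call. = FALSE)
    if (iv$time > t_end)
      stop("regime '", rg$label, "': intervention at t=", iv$time,
           " min is beyond t_end=", t_end, " min", call. = FALSE)
  }
  regime(rg$label, rg$interventions)
}

#' Read a regime from a YAML or JSON specification file
#'
#' The file lists `label` and `interventions`, each with fields
#' `kind`, `target` (or `drug` when a catalogue is supplied), `value` (or
#' `dosage`) and `time`.
#'
#' @param path Path to the YAML/JSON file.
#' @param catalogue Optional `drug_catalogue` used to resolve `drug` entries.
#' @return A [regime()].
#' @export
read_regime <- function(path, catalogue = NULL) {
  if (!file.exists(path)) stop("regime file not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)  # YAML superset also parses JSON
  label <- if (!is.null(spec$label)) spec$label else "Regime"
  ivs <- lapply(spec$interventions, function(e) {
    if (!is.null(e$drug)) {
      if (is.null(catalogue))
        stop("regime entry names a drug but no catalogue was supplied",
             call. = FALSE)
      return(make_dose(catalogue, e$drug,
                       dosage = e$dosage %||% e$value,
                       time = e$time %||% 0))
    }
    intervention(e$kind, e$target, e$value, e$time %||% 0)
  })
  regime(label, ivs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
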