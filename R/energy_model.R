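PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# kcal/mol sentinel for disallowed features; kept finite-free (never NaN).
INF_ENERGY <- Inf

#' Default nearest-neighbor energy parameters (37 degrees C)
#'
#' A documented Turner-style subset: 6x6 canonical stack table,
#' hairpin/bulge/internal loop length tables (sizes up to 30, with a
#' Jacobson-Stockmayer logarithmic extrapolation beyond), a Ninio
#' asymmetry term for internal loops, affine multiloop coefficients, and
#' an affine pseudoknot penalty (initiation per crossing component,
#' penalty per band, penalty per unpaired base under a band span).
#' Dangling ends and coaxial stacking are omitted. Parameters are derived
#' for 37 degrees C and 1 M NaCl and are fully replaceable through
#' [read_energy_parameters()].
#'
#' @return An `energy_parameters` object.
#' @export
default_energy_parameters <- function() {
  cached <- get0("default37", envir = .covfold_cache)
  if (!is.null(cached)) return(cached)
  out <- build_default_parameters()
  assign("default37", out, envir = .covfold_cache)
  out
}

.covfold_cache <- new.env(parent = emptyenv())

build_default_parameters <- function() {
  stack <- matrix(c(
    # inner:  AU     UA     CG     GC     GU     UG     closing:
            -0.9,  -1.1,  -2.2,  -2.1,  -0.6,  -1.4,   # AU
            -1.3,  -0.9,  -2.4,  -2.1,  -1.0,  -1.3,   # UA
            -2.1,  -2.1,  -3.3,  -2.4,  -1.4,  -2.1,   # CG
            -2.4,  -2.2,  -3.4,  -3.3,  -1.5,  -2.5,   # GC
            -1.3,  -1.4,  -2.5,  -2.1,  -0.5,   1.3,   # GU
            -1.0,  -0.6,  -1.5,  -1.4,   0.3,  -0.5),  # UG
    nrow = 6L, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  js <- function(base, base_size, sizes) base + 1.75 * 0.616 * log(sizes / base_size)
  hairpin <- c(INF_ENERGY, INF_ENERGY, js(5.4, 3, 3:30))
  bulge <- c(3.8, js(2.8, 2, 2:30))
  internal <- c(INF_ENERGY, js(1.7, 2, 2:30))
  energy_parameters(
    temperature = 37,
    stack = stack,
    hairpin = hairpin,
    bulge = bulge,
    internal = internal,
    extrapolation = 1.75 * 0.616,
    ninio = c(slope = 0.6, max = 3.0),
    multi = c(closing = 3.4, branch = 0.4, unpaired = 0.0),
    pk = c(init = 9.6, band = 0.2, unpaired = 0.0)
  )
}

#' Construct an energy parameter set
#'
#' @param temperature Temperature tag in degrees C.
#' @param stack 6x6 matrix (rows: closing pair, cols: inner pair, order
#'   `AU UA CG GC GU UG`), kcal/mol.
#' @param hairpin,bulge,internal Length tables indexed by loop size 1..30
#'   (disallowed sizes `Inf`).
#' @param extrapolation Coefficient `c` of the `E(30) + c log(L/30)`
#'   extension beyond table range.
#' @param ninio Named vector `slope`, `max` for internal-loop asymmetry.
#' @param multi Named vector `closing`, `branch`, `unpaired` (affine
#'   multiloop model).
#' @param pk Named vector `init`, `band`, `unpaired` (affine pseudoknot
#'   penalties).
#' @return An `energy_parameters` object; incomplete tables are an error.
#' @export
energy_parameters <- function(temperature, stack, hairpin, bulge, internal,
                              extrapolation, ninio, multi, pk) {
  stack <- as.matrix(stack)
  if (!identical(dim(stack), c(6L, 6L))) {
    stop("stack table must be 6x6 over ", paste(PAIR_TYPES, collapse = " "),
         call. = FALSE)
  }
  dimnames(stack) <- list(PAIR_TYPES, PAIR_TYPES)
  if (any(!is.finite(stack))) {
    bad <- which(!is.finite(stack), arr.ind = TRUE)[1L, ]
    stop("missing stack energy for ", PAIR_TYPES[bad[1L]], " on ",
         PAIR_TYPES[bad[2L]], call. = FALSE)
  }
  for (nm in c("hairpin", "bulge", "internal")) {
    tab <- get(nm)
    if (length(tab) != 30L) {
      stop(nm, " table must cover sizes 1..30 (got ", length(tab), ")",
           call. = FALSE)
    }
  }
  if (any(!is.finite(hairpin[3:30]))) {
    stop("hairpin table incomplete for sizes 3..30", call. = FALSE)
  }
  ninio <- c(slope = unname(ninio["slope"]), max = unname(ninio["max"]))
  multi <- c(closing = unname(multi["closing"]), branch = unname(multi["branch"]),
             unpaired = unname(multi["unpaired"]))
  pk <- c(init = unname(pk["init"]), band = unname(pk["band"]),
          unpaired = unname(pk["unpaired"]))
  if (anyNA(c(ninio, multi, pk))) {
    stop("ninio/multi/pk coefficients incomplete", call. = FALSE)
  }
  structure(list(temperature = temperature, stack = stack, hairpin = hairpin,
                 bulge = bulge, internal = internal,
                 extrapolation = extrapolation, ninio = ninio, multi = multi,
                 pk = pk),
            class = "energy_parameters")
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat("<energy_parameters> ", x$temperature, " C; stack range [",
      sprintf("%.1f", min(x$stack)), ", ", sprintf("%.1f", max(x$stack)),
      "] kcal/mol; pk init ", x$pk[["init"]], ", band ", x$pk[["band"]],
      "\n", sep = "")
  invisible(x)
}

#' Read an energy parameter file
#'
#' Plain-text sectioned format (written by [write_energy_parameters()]):
#' `#` comments; sections `TEMPERATURE`, `STACK` (36 lines
#' `closing inner energy`), `HAIRPIN`/`BULGE`/`INTERNAL` (lines
#' `size energy`, `inf` allowed), `EXTRAPOLATION`, `NINIO`, `MULTI`,
#' `PSEUDOKNOT`. Missing entries are an error, not silent defaults.
#'
#' @param path Path to a parameter file, or the builtin name
#'   `"default37"`.
#' @return An `energy_parameters` object.
#' @export
read_energy_parameters <- function(path) {
  if (identical(path, "default37")) return(default_energy_parameters())
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  section <- NA_character_
  num <- function(s) ifelse(tolower(s) %in% c("inf", "+inf"), Inf,
                            suppressWarnings(as.numeric(s)))
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  tabs <- list(HAIRPIN = rep(NA_real_, 30L), BULGE = rep(NA_real_, 30L),
               INTERNAL = rep(NA_real_, 30L))
  temperature <- NA_real_; extrapolation <- NA_real_
  ninio <- NULL; multi <- NULL; pk <- NULL
  headers <- c("TEMPERATURE", "STACK", "HAIRPIN", "BULGE", "INTERNAL",
               "EXTRAPOLATION", "NINIO", "MULTI", "PSEUDOKNOT")
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    lineno <- keep[k]
    if (tk[1L] %in% headers) {
      section <- tk[1L]
      if (section == "TEMPERATURE" && length(tk) > 1L) temperature <- num(tk[2L])
      if (section == "EXTRAPOLATION" && length(tk) > 1L) extrapolation <- num(tk[2L])
      if (section == "NINIO" && length(tk) == 3L) {
        ninio <- c(slope = num(tk[2L]), max = num(tk[3L]))
      }
      if (section == "MULTI" && length(tk) == 4L) {
        multi <- c(closing = num(tk[2L]), branch = num(tk[3L]),
                   unpaired = num(tk[4L]))
      }
      if (section == "PSEUDOKNOT" && length(tk) == 4L) {
        pk <- c(init = num(tk[2L]), band = num(tk[3L]), unpaired = num(tk[4L]))
      }
      next
    }
    if (is.na(section)) {
      stop("parameter file line ", lineno, ": data before any section header",
           call. = FALSE)
    }
    if (section == "STACK") {
      if (length(tk) != 3L || !(tk[1L] %in% PAIR_TYPES) ||
          !(tk[2L] %in% PAIR_TYPES)) {
        stop("parameter file line ", lineno, ": expected '<pair> <pair> <energy>'",
             call. = FALSE)
      }
      stack[tk[1L], tk[2L]] <- num(tk[3L])
    } else if (section %in% names(tabs)) {
      sz <- suppressWarnings(as.integer(tk[1L]))
      if (length(tk) != 2L || is.na(sz) || sz < 1L || sz > 30L) {
        stop("parameter file line ", lineno, ": expected '<size 1..30> <energy>'",
             call. = FALSE)
      }
      tabs[[section]][sz] <- num(tk[2L])
    } else {
      stop("parameter file line ", lineno, ": unexpected data in section ",
           section, call. = FALSE)
    }
  }
  if (is.na(stack)[1L] || anyNA(stack)) {
    bad <- which(is.na(stack), arr.ind = TRUE)[1L, ]
    stop("missing STACK entry for ", PAIR_TYPES[bad[1L]], " on ",
         PAIR_TYPES[bad[2L]], call. = FALSE)
  }
  # unlisted loop sizes are disallowed
  for (nm in names(tabs)) tabs[[nm]][is.na(tabs[[nm]])] <- Inf
  if (is.null(ninio) || is.null(multi) || is.null(pk) || is.na(temperature) ||
      is.na(extrapolation)) {
    stop("parameter file incomplete: needs TEMPERATURE, EXTRAPOLATION, ",
         "NINIO, MULTI and PSEUDOKNOT lines", call. = FALSE)
  }
  energy_parameters(temperature, stack, tabs$HAIRPIN, tabs$BULGE,
                    tabs$INTERNAL, extrapolation, ninio, multi, pk)
}

#' Write an energy parameter file
#'
#' @param params An `energy_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly. `read_energy_parameters()` on the result is
#'   an identity round trip.
#' @export
write_energy_parameters <- function(params, path) {
  stopifnot(inherits(params, "energy_parameters"))
  fmt <- function(x) ifelse(is.infinite(x), "inf", sprintf("%.6f", x))
  out <- c("# covfold energy parameters (kcal/mol)",
           paste("TEMPERATURE", params$temperature),
           "STACK")
  for (p in PAIR_TYPES) for (q in PAIR_TYPES) {
    out <- c(out, paste(p, q, fmt(params$stack[p, q])))
  }
  for (nm in c("hairpin", "bulge", "internal")) {
    out <- c(out, toupper(nm))
    tab <- params[[nm]]
    for (sz in which(is.finite(tab))) out <- c(out, paste(sz, fmt(tab[sz])))
  }
  out <- c(out,
           paste("EXTRAPOLATION", fmt(params$extrapolation)),
           paste("NINIO", fmt(params$ninio[["slope"]]), fmt(params$ninio[["max"]])),
           paste("MULTI", fmt(params$multi[["closing"]]),
                 fmt(params$multi[["branch"]]), fmt(params$multi[["unpaired"]])),
           paste("PSEUDOKNOT", fmt(params$pk[["init"]]), fmt(params$pk[["band"]]),
                 fmt(params$pk[["unpaired"]])))
  writeLines(out, path)
  invisible(path)
}

# Pair type index of bases b1, b2 (characters); 0 if non-canonical.
pair_type <- function(b1, b2) {
  key <- paste0(b1, b2)
  m <- match(key, PAIR_TYPES)
  ifelse(is.na(m), 0L, m)
}

loop_table <- function(tab, size, coef) {
  if (size < 1L) return(INF_ENERGY)
  if (size <= 30L) return(tab[size])
  tab[30L] + coef * log(size / 30)
}

#' Free energy of a single loop
#'
#' @param params An `energy_parameters` object.
#' @param kind One of `"hairpin"`, `"stack"`, `"bulge"`, `"internal"`,
#'   `"multiloop"`, `"pk"`.
#' @param size Loop size: unpaired bases in a hairpin or bulge.
#' @param closing,inner Pair types (strings like `"GC"`) for stacks,
#'   bulges and internal loops. Non-canonical pairs give `Inf`.
#' @param l1,l2 Unpaired counts on the two sides of an internal loop.
#' @param branches,unpaired Multiloop branch count (excluding the closing
#'   pair) and unpaired base count.
#' @param components,bands,pk_unpaired Pseudoknot counts: crossing
#'   components, bands, and unpaired bases under band spans.
#' @return Energy in kcal/mol; `Inf` for disallowed geometry (hairpin
#'   loop shorter than 3, non-canonical pair).
#' @export
loop_energy <- function(params,
                        kind = c("hairpin", "stack", "bulge", "internal",
                                 "multiloop", "pk"),
                        size = NULL, closing = NULL, inner = NULL,
                        l1 = NULL, l2 = NULL,
                        branches = NULL, unpaired = NULL,
                        components = 1, bands = 0, pk_unpaired = 0) {
  kind <- match.arg(kind)
  switch(kind,
    hairpin = {
      if (size < 3L) INF_ENERGY else
        loop_table(params$hairpin, size, params$extrapolation)
    },
    stack = {
      if (!(closing %in% PAIR_TYPES) || !(inner %in% PAIR_TYPES)) INF_ENERGY
      else params$stack[closing, inner]
    },
    bulge = {
      if (!(closing %in% PAIR_TYPES) || !(inner %in% PAIR_TYPES)) INF_ENERGY
      else loop_table(params$bulge, size, params$extrapolation)
    },
    internal = {
      if (!(closing %in% PAIR_TYPES) || !(inner %in% PAIR_TYPES)) INF_ENERGY
      else {
        loop_table(params$internal, l1 + l2, params$extrapolation) +
          min(params$ninio[["max"]], params$ninio[["slope"]] * abs(l1 - l2))
      }
    },
    multiloop = {
      params$multi[["closing"]] + params$multi[["branch"]] * branches +
        params$multi[["unpaired"]] * unpaired
    },
    pk = {
      params$pk[["init"]] * components + params$pk[["band"]] * bands +
        params$pk[["unpaired"]] * pk_unpaired
    }
  )
}

#' Free energy of a complete structure
#'
#' Decomposes a (possibly pseudoknotted, density-2/bisecondary) structure
#' into loops and sums their energies. Crossing structures are first
#' split into two pseudoknot-free layers (first-fit, see
#' [split_layers()]); the base layer is scored with the nested loop
#' model treating bases paired in the added layer as unpaired; the added
#' layer, whose pairs all cross the base layer and therefore form
#' pseudoknot bands, is scored by its stacking terms alone (band loops
#' are covered by the affine penalty, not by hairpin/internal
#' initiation); and an affine pseudoknot term (initiation per crossing
#' component, penalty per band, penalty per unpaired base under a band
#' span) is added. The empty
#' structure has energy 0; a non-canonical pair yields the `Inf` sentinel
#' with a warning.
#'
#' @param seq RNA sequence string (A/C/G/U).
#' @param st An [rna_structure()] (or dot-bracket string).
#' @param params Energy parameters; default [default_energy_parameters()].
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(seq, st, params = default_energy_parameters()) {
  if (is.character(st)) st <- parse_dotbracket(st)
  stopifnot(inherits(st, "rna_structure"))
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(bases) != st$length) {
    stop("sequence length ", length(bases), " != structure length ",
         st$length, call. = FALSE)
  }
  pairs <- st$pairs
  if (!nrow(pairs)) return(0)
  pt <- pair_type(bases[pairs[, 1L]], bases[pairs[, 2L]])
  if (any(pt == 0L)) {
    bad <- which(pt == 0L)[1L]
    warning(sprintf("non-canonical pair %s.%s at (%d, %d)",
                    bases[pairs[bad, 1L]], bases[pairs[bad, 2L]],
                    pairs[bad, 1L], pairs[bad, 2L]), call. = FALSE)
    return(INF_ENERGY)
  }
  lay <- split_layers(pairs)
  e <- nested_layer_energy(bases, pairs[lay$layer1, , drop = FALSE], params) +
    stack_only_energy(bases, pairs[lay$layer2, , drop = FALSE], params)
  if (length(lay$layer2)) {
    cm <- crossing_matrix(pairs)
    comp <- crossing_components(cm)
    bands <- structure_bands(pairs)
    paired <- as.vector(pairs)
    covered <- logical(st$length)
    for (b in bands) covered[min(b[, 1L]):max(b[, 2L])] <- TRUE
    pk_unp <- sum(covered[setdiff(which(covered), paired)])
    e <- e + loop_energy(params, "pk", components = comp,
                         bands = length(bands), pk_unpaired = pk_unp)
  }
  e
}

# Stacking-only energy of the added (crossing) layer: every pair of that
# layer crosses the base layer, so its pairs belong to pseudoknot bands,
# which are scored by their stacking terms alone (their loops are covered
# by the affine pseudoknot penalty, not by hairpin/internal initiation).
stack_only_energy <- function(bases, pairs, params) {
  pairs <- normalize_pairs(pairs)
  if (!nrow(pairs)) return(0)
  pt <- pair_type(bases[pairs[, 1L]], bases[pairs[, 2L]])
  key <- paste(pairs[, 1L], pairs[, 2L])
  row_of <- stats::setNames(seq_len(nrow(pairs)), key)
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    inner <- row_of[paste(pairs[r, 1L] + 1L, pairs[r, 2L] - 1L)]
    if (!is.na(inner)) {
      total <- total + loop_energy(params, "stack",
                                   closing = PAIR_TYPES[pt[r]],
                                   inner = PAIR_TYPES[pt[inner]])
    }
  }
  total
}

# Number of connected components (size >= 2) in the crossing graph.
crossing_components <- function(cm) {
  m <- nrow(cm)
  if (!m) return(0L)
  seen <- logical(m)
  comps <- 0L
  for (s in seq_len(m)) {
    if (seen[s] || !any(cm[s, ])) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(cm[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# Loop-decomposition energy of one pseudoknot-free layer; bases paired in
# the other layer are transparent (count as unpaired).
nested_layer_energy <- function(bases, pairs, params) {
  pairs <- normalize_pairs(pairs)
  m <- nrow(pairs)
  if (!m) return(0)
  pt <- pair_type(bases[pairs[, 1L]], bases[pairs[, 2L]])
  # parent of each pair: smallest enclosing pair in the same layer
  total <- 0
  for (r in seq_len(m)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    inside <- which(pairs[, 1L] > i & pairs[, 2L] < j)
    if (length(inside)) {
      # direct children: not enclosed by another inside pair
      direct <- inside[vapply(inside, function(q) {
        !any(pairs[inside, 1L] < pairs[q, 1L] & pairs[inside, 2L] > pairs[q, 2L])
      }, logical(1))]
    } else direct <- integer(0)
    nc <- length(direct)
    if (nc == 0L) {
      total <- total + loop_energy(params, "hairpin", size = j - i - 1L)
    } else if (nc == 1L) {
      k <- pairs[direct, 1L]; l <- pairs[direct, 2L]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + loop_energy(params, "stack",
                                     closing = PAIR_TYPES[pt[r]],
                                     inner = PAIR_TYPES[pt[direct]])
      } else if (l1 == 0L || l2 == 0L) {
        total <- total + loop_energy(params, "bulge", size = l1 + l2,
                                     closing = PAIR_TYPES[pt[r]],
                                     inner = PAIR_TYPES[pt[direct]])
      } else {
        total <- total + loop_energy(params, "internal", l1 = l1, l2 = l2,
                                     closing = PAIR_TYPES[pt[r]],
                                     inner = PAIR_TYPES[pt[direct]])
      }
    } else {
      unp <- (j - i - 1L) -
        sum(pairs[direct, 2L] - pairs[direct, 1L] + 1L)
      # closing helix counts as a branch (Zuker convention)
      total <- total + loop_energy(params, "multiloop", branches = nc + 1L,
                                   unpaired = unp)
    }
    if (!is.finite(total)) return(INF_ENERGY)
  }
  total
}
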