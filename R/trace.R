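# Analytic shape tracing and parameter accounting.

.ceilHalf <- function(x) as.integer(ceiling(x / 2))

#' Analytic shape trace of a configuration
#'
#' Computes, without building the network or touching any tensor, the
#' input and output dimensions of every stage: the stem, each main stage
#' (shape preserving) and each downsampling layer (sides halved with the
#' ceiling convention, channels doubled). For the reference configuration
#' this reproduces the published transition 224x224x3 -> 56x56x96 ->
#' 28x28x192 -> 14x14x384 -> 7x7x768.
#'
#' @param config a [MACNeXtConfig-class].
#' @return a data.frame with columns `stage`, `inHeight`, `inWidth`,
#'   `inChannels`, `outHeight`, `outWidth`, `outChannels`.
#' @examples
#' traceShapes(macnextConfig())
#' @export
traceShapes <- function(config) {
  validObject(config)
  rows <- list()
  h <- config@inputHeight
  w <- config@inputWidth
  c <- config@inputChannels
  add <- function(stage, ih, iw, ic, oh, ow, oc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, inHeight = ih, inWidth = iw, inChannels = ic,
      outHeight = oh, outWidth = ow, outChannels = oc,
      stringsAsFactors = FALSE
    )
  }
  oh <- .ceilHalf(.ceilHalf(h))
  ow <- .ceilHalf(.ceilHalf(w))
  oc <- config@stemWidths[2L]
  add("stem", h, w, c, oh, ow, oc)
  h <- oh; w <- ow; c <- oc
  nstage <- length(config@stageWidths)
  for (s in seq_len(nstage)) {
    f <- config@stageWidths[s]
    add(sprintf("stage%d", s), h, w, f, h, w, f)
    if (s < nstage) {
      oh <- .ceilHalf(h); ow <- .ceilHalf(w)
      add(sprintf("ds%d", s), h, w, f, oh, ow, 2L * f)
      h <- oh; w <- ow
    }
  }
  do.call(rbind, rows)
}

#' Observed shape trace from a forward pass
#'
#' Runs a batch through a built model component by component and records
#' the tensor dimensions actually produced, in the same layout as
#' [traceShapes()]. The two must agree stage by stage for any valid
#' configuration.
#'
#' @param model a [MACNeXtModel-class].
#' @param x an image array (defaults to a single zero image of the
#'   configured size).
#' @return a data.frame in the [traceShapes()] layout.
#' @export
observedTrace <- function(model, x = NULL) {
  cfg <- model@config
  if (is.null(x)) {
    x <- array(0, dim = c(cfg@inputHeight, cfg@inputWidth,
                          cfg@inputChannels, 1L))
  }
  x <- .as4d(x)
  rows <- list()
  add <- function(stage, din, dout) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, inHeight = din[1L], inWidth = din[2L],
      inChannels = din[3L], outHeight = dout[1L], outWidth = dout[2L],
      outChannels = dout[3L], stringsAsFactors = FALSE
    )
  }
  t0 <- dim(x)
  t <- .stemForwardFull(model@layers$stem, x, FALSE)$out
  add("stem", t0, dim(t))
  L <- model@layers
  nstage <- length(L$stages)
  for (s in seq_len(nstage)) {
    din <- dim(t)
    for (b in seq_along(L$stages[[s]]$blocks)) {
      t <- .blockForwardFull(L$stages[[s]]$blocks[[b]], t, FALSE)$out
    }
    add(sprintf("stage%d", s), din, dim(t))
    if (!is.null(L$stages[[s]]$down)) {
      din <- dim(t)
      t <- .downForwardFull(L$stages[[s]]$down, t, FALSE)$out
      add(sprintf("ds%d", s), din, dim(t))
    }
  }
  do.call(rbind, rows)
}

.countConv <- function(k, cin, cout, groups) as.numeric(k * k * (cin / groups) * cout)

# Closed-form per-layer parameter inventory computed algebraically from the
# configuration (no arrays allocated). Grouped convolutions contribute
# k^2 * channelsPerGroup * Cout; batch norm 2C; the FC layer C*n + n.
.closedFormEntries <- function(cfg) {
  cpg <- cfg@channelsPerGroup
  sw <- cfg@stemWidths
  entries <- list()
  add <- function(label, count) {
    entries[[length(entries) + 1L]] <<- data.frame(
      layer = label, count = count, stringsAsFactors = FALSE
    )
  }
  add("stem.conv1", .countConv(3, cfg@inputChannels, sw[1L], 1))
  add("stem.bn1", 2 * sw[1L])
  add("stem.conv2", .countConv(3, sw[1L], sw[2L], sw[1L] / cpg))
  add("stem.bn2", 2 * sw[2L])
  nstage <- length(cfg@stageWidths)
  for (s in seq_len(nstage)) {
    f <- cfg@stageWidths[s]
    g <- f / cpg
    g2 <- 2 * f / cpg
    for (b in seq_len(cfg@stageRepeats[s])) {
      pre <- sprintf("stage%d.block%d", s, b)
      add(paste0(pre, ".gc3"), .countConv(3, f, f, g))
      add(paste0(pre, ".bnA"), 2 * f)
      add(paste0(pre, ".gc1"), .countConv(1, f, f, g))
      add(paste0(pre, ".bnB"), 2 * f)
      add(paste0(pre, ".expand"),
          .countConv(1, 2 * f, 2 * f, if (cfg@expansionGrouped) g2 else 1))
      add(paste0(pre, ".squeeze"),
          .countConv(1, 2 * f, f, if (cfg@squeezeGrouped) g2 else 1))
      add(paste0(pre, ".bnC"), 2 * f)
      add(paste0(pre, ".brG"), .countConv(1, f, f, g))
      add(paste0(pre, ".brR"), .countConv(1, f, f, g))
      add(paste0(pre, ".bnD"), 2 * f)
    }
    if (s < nstage) {
      add(sprintf("stage%d.down.conv", s), .countConv(3, f, 2 * f, g))
      add(sprintf("stage%d.down.bn", s), 2 * (2 * f))
    }
  }
  flast <- cfg@stageWidths[nstage]
  add("head.fc", flast * cfg@numClasses + cfg@numClasses)
  do.call(rbind, entries)
}

#' Count learnable parameters
#'
#' Either evaluates the closed-form per-layer algebra
#' (`mode = "closed_form"`) or builds the network and enumerates every
#' learnable scalar in it (`mode = "built"`). The two totals must agree
#' exactly; for the reference configuration both give 4,436,808 (4.4
#' million). Convolutions carry no bias (each is followed by batch norm);
#' the FC layer carries one bias per class.
#'
#' @param config a [MACNeXtConfig-class].
#' @param mode `"closed_form"` or `"built"`.
#' @return a list with `entries` (data.frame of per-layer counts) and
#'   `total`.
#' @examples
#' countParameters(macnextConfig())$total
#' @export
countParameters <- function(config, mode = c("closed_form", "built")) {
  mode <- match.arg(mode)
  validObject(config)
  if (mode == "closed_form") {
    entries <- .closedFormEntries(config)
  } else {
    model <- buildModel(config)
    params <- .collectParams(model)
    entries <- data.frame(
      layer = names(params),
      count = vapply(params, function(p) as.numeric(length(p)), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(entries = entries, total = sum(entries$count))
}
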