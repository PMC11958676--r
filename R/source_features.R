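#' Desikan-Killiany cortical parcel names
#'
#' The 68 cortical labels of the Desikan-Killiany atlas (34 per
#' hemisphere), prefixed `lh_` / `rh_`.
#'
#' @return character vector of length 68.
#' @export
dk_labels <- function() {
  base <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
            "cuneus", "entorhinal", "fusiform", "inferiorparietal",
            "inferiortemporal", "isthmuscingulate", "lateraloccipital",
            "lateralorbitofrontal", "lingual", "medialorbitofrontal",
            "middletemporal", "parahippocampal", "paracentral",
            "parsopercularis", "parsorbitalis", "parstriangularis",
            "pericalcarine", "postcentral", "posteriorcingulate",
            "precentral", "precuneus", "rostralanteriorcingulate",
            "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
            "superiortemporal", "supramarginal", "frontalpole",
            "temporalpole", "transversetemporal", "insula")
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Read a label-to-network map
#'
#' A network map assigns every source label to one large-scale
#' resting-state network (VSN, SMN, DAN, VAN, LBN, FPN, DMN, or DGN for
#' deep gray), carries its hemisphere, and flags membership of the
#' auditory network (AUN), which overlaps the cortical networks.
#'
#' @param path TSV file with columns `label`, `network`, `hemisphere`,
#'   `aun` (TRUE/FALSE).
#' @param labels labels that must all be covered by the map; unknown or
#'   missing labels raise an error.
#' @return data.frame of class `network_map`.
#' @export
read_network_map <- function(path, labels = NULL) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("label", "network", "hemisphere", "aun")
  if (!all(required %in% names(m))) {
    stop("network map must have columns: ", paste(required, collapse = ", "))
  }
  m$aun <- as.logical(m$aun)
  if (!is.null(labels)) {
    missing <- setdiff(labels, m$label)
    if (length(missing)) {
      stop("network map does not cover labels: ",
           paste(missing, collapse = ", "))
    }
    m <- m[match(labels, m$label), ]
  }
  class(m) <- c("network_map", "data.frame")
  m
}

#' Default Desikan-Killiany network map
#'
#' Ships with the package as an editable TSV
#' (`system.file("extdata", "dk_network_map.tsv", package = "batseeg")`):
#' the standard seven-network cortical assignment of the DK-68 parcels
#' plus an auditory-network flag covering superior/transverse temporal,
#' supramarginal, superior parietal, middle temporal, temporal pole,
#' banks of the superior temporal sulcus and insula. The atlas has no
#' subcortical parcels, so no label carries the deep-gray (DGN) network
#' by default.
#'
#' @return a `network_map` data.frame covering all 68 DK labels.
#' @export
default_network_map <- function() {
  read_network_map(system.file("extdata", "dk_network_map.tsv",
                               package = "batseeg"),
                   labels = dk_labels())
}

# network map for generic reduced atlases used in simulations/tests:
# labels are split round-robin across the requested networks and the first
# n_aun labels are flagged auditory
toy_network_map <- function(labels, networks = c("AUN", "DMN"),
                            n_aun = sum(rep_len(networks,
                                                length(labels)) == "AUN")) {
  m <- data.frame(label = labels,
                  network = rep_len(networks, length(labels)),
                  hemisphere = label_hemisphere(labels),
                  aun = FALSE, stringsAsFactors = FALSE)
  m$aun <- m$network == "AUN"
  class(m) <- c("network_map", "data.frame")
  m
}

#' Source-label band power features
#'
#' Per epoch, per Desikan-Killiany label and per band: mean Welch PSD over
#' the band's bins (the same estimator as the sensor-space band power).
#' For the full 68-label atlas and five bands this yields 340 columns.
#'
#' @param lts a `label_time_series` (see [simulate_label_signals()]), or any
#'   object with fields `data` (epochs x labels x samples), `label_names`,
#'   `sampling_rate`.
#' @param scheme a [band_scheme()].
#' @param psd a [psd_settings()] object.
#' @param known_labels labels accepted by the atlas; defaults to the DK-68
#'   set when the data has 68 labels, otherwise the data's own names.
#'   Unknown label names are rejected.
#' @return a [feature_matrix()] with family `source_power`, column order
#'   bands outer, labels inner.
#' @export
label_band_power <- function(lts, scheme = band_scheme(),
                             psd = psd_settings(),
                             known_labels = NULL) {
  d <- dim(lts$data)
  labs <- lts$label_names
  if (is.null(known_labels)) {
    known_labels <- if (d[2] == 68) dk_labels() else labs
  }
  unknown <- setdiff(labs, known_labels)
  if (length(unknown)) {
    stop("unknown label names: ", paste(unknown, collapse = ", "))
  }
  n_ep <- d[1]; n_lab <- d[2]
  ep <- epochs_psd(lts$data, lts$sampling_rate, psd)
  n_bands <- nrow(scheme)
  pow <- matrix(NA_real_, n_ep, n_lab * n_bands)
  for (i in seq_len(n_bands)) {
    bb <- band_bins(ep$freqs, scheme$f_lo[i], scheme$f_hi[i])
    if (!any(bb)) stop("band ", scheme$band[i], " contains no PSD bins")
    block <- (i - 1) * n_lab + seq_len(n_lab)
    pow[, block] <- rowMeans(ep$power[, , bb, drop = FALSE], dims = 2)
  }
  band_rep <- rep(scheme$band, each = n_lab)
  lab_rep <- rep(labs, times = n_bands)
  meta <- data.frame(feature = paste0("src_", band_rep, "_", lab_rep),
                     family = "source_power", band = band_rep,
                     unit = lab_rep, hemisphere = label_hemisphere(lab_rep),
                     stringsAsFactors = FALSE)
  rows <- data.frame(subject_id = lts$subject_id, epoch = seq_len(n_ep),
                     group = if (!is.null(lts$group)) lts$group
                             else NA_character_,
                     stringsAsFactors = FALSE)
  drop_bad_rows(feature_matrix(pow, meta, rows))
}
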