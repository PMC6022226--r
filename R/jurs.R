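# Charged-partial-surface-area (CPSA) descriptors in the Stanton-Jurs
# convention: combinations of per-atom solvent-accessible surface area
# with Gasteiger partial charges.

#' Jurs charged-partial-surface-area descriptors
#'
#' Standard CPSA family.  With `SA_i` the per-atom solvent-accessible
#' areas, `q_i` the partial charges, `S = sum(SA_i)`, `Q+ = sum(q_i > 0)`
#' and `Q- = sum(q_i < 0)`:
#' \itemize{
#'   \item PPSA_1 / PNSA_1: partial positive/negative surface area (atoms
#'     with zero charge count to the positive set, so PPSA_1 + PNSA_1 = S);
#'   \item PPSA_2 / PNSA_2: total charge weighted, PPSA_1 * Q+ etc.;
#'   \item PPSA_3 / PNSA_3: atomic charge weighted, sum(SA_i q_i) over the
#'     positive / negative set (PNSA_3 <= 0 by construction);
#'   \item DPSA_k = PPSA_k - PNSA_k; FPSA_k / FNSA_k = PPSA_k / S etc.;
#'     WPSA_k / WNSA_k = PPSA_k * S / 1000 etc.;
#'   \item RPCG / RNCG: largest positive (most negative) charge over Q+
#'     (Q-); RPCS / RNCS: surface area of that atom times RPCG (RNCG);
#'   \item TASA / TPSA: areas of atoms with |q| < 0.2 and |q| >= 0.2;
#'     RASA / RPSA: the same as fractions of S.
#' }
#'
#' @param areas per-atom surface areas from [sasa()].
#' @param charges per-atom partial charges (same atom order), or a charged
#'   `qsar_molecule`.
#' @return named numeric vector of the 29 CPSA values, names prefixed
#'   `Jurs_`.
#' @export
jurs_descriptors <- function(areas, charges) {
  if (inherits(charges, "qsar_molecule"))
    charges <- charges$atoms$partial_charge
  if (length(areas) != length(charges))
    stop("areas and charges cover different atom sets (",
         length(areas), " vs ", length(charges), ")")
  sa <- as.numeric(areas); q <- as.numeric(charges)
  S <- sum(sa)
  pos <- q >= 0; neg <- q < 0
  qpos <- sum(q[q > 0]); qneg <- sum(q[neg])
  ppsa1 <- sum(sa[pos]); pnsa1 <- sum(sa[neg])
  ppsa2 <- ppsa1 * qpos; pnsa2 <- pnsa1 * qneg
  ppsa3 <- sum(sa[q > 0] * q[q > 0]); pnsa3 <- sum(sa[neg] * q[neg])
  rpcg <- if (qpos > 0) max(q) / qpos else 0
  rncg <- if (qneg < 0) min(q) / qneg else 0
  rpcs <- if (qpos > 0) sa[which.max(q)] * rpcg else 0
  rncs <- if (qneg < 0) sa[which.min(q)] * rncg else 0
  polar <- abs(q) >= 0.2
  tasa <- sum(sa[!polar]); tpsa <- sum(sa[polar])
  out <- c(PPSA_1 = ppsa1, PPSA_2 = ppsa2, PPSA_3 = ppsa3,
           PNSA_1 = pnsa1, PNSA_2 = pnsa2, PNSA_3 = pnsa3,
           DPSA_1 = ppsa1 - pnsa1, DPSA_2 = ppsa2 - pnsa2,
           DPSA_3 = ppsa3 - pnsa3,
           FPSA_1 = ppsa1 / S, FPSA_2 = ppsa2 / S, FPSA_3 = ppsa3 / S,
           FNSA_1 = pnsa1 / S, FNSA_2 = pnsa2 / S, FNSA_3 = pnsa3 / S,
           WPSA_1 = ppsa1 * S / 1000, WPSA_2 = ppsa2 * S / 1000,
           WPSA_3 = ppsa3 * S / 1000,
           WNSA_1 = pnsa1 * S / 1000, WNSA_2 = pnsa2 * S / 1000,
           WNSA_3 = pnsa3 * S / 1000,
           RPCG = rpcg, RNCG = rncg, RPCS = rpcs, RNCS = rncs,
           TASA = tasa, TPSA = tpsa, RASA = tasa / S, RPSA = tpsa / S)
  setNames(out, paste0("Jurs_", names(out)))
}
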