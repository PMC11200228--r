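# Molecular descriptors and the QED drug-likeness score.
#
# QED (quantitative estimate of drug-likeness) is the weighted geometric mean
# of eight desirability functions fitted to the distributions of approved
# oral drugs: molecular weight, ALOGP, H-bond acceptors and donors, polar
# surface area, rotatable bonds, aromatic rings and structural-alert hits.
# The asymmetric-double-sigmoid (ADS) parameters, descriptor weights and the
# acceptor/alert substructure definitions below are the published constants
# of that model. OpenBabel supplies ALOGP, TPSA, HBD and SMARTS matching;
# the package's own graph supplies MW and aromatic-ring counts.

# ADS parameters: a, b, c, d, e, f, dmax per descriptor
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)

.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# H-bond acceptor environments (atom-count patterns)
.QED_ACCEPTOR_SMARTS <- c(
  "[oH0X2]", "[OH1X2v2]", "[OH0X2v2]", "[OH0X1v2]", "[O-X1]",
  "[SH0X2v2]", "[SH0X1v2]", "[S-X1]", "[nH0X2]", "[NH0X1v3]",
  "[$([N+0X3v3]);!$(N[C,S]=O)]"
)

.QED_HBD_SMARTS <- "[#7,#8;!H0]"
# strict rotatable-bond definition (amides, trihalomethyl and tBu excluded)
.QED_ROTB_SMARTS <- paste0(
  "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)",
  "&!$(C([CH3])([CH3])[CH3])&!$([CD3](=[N,O,S])-!@[#7,O,S!D1])",
  "&!$([#7,O,S!D1]-!@[CD3]=[N,O,S])&!$([CD3](=[N+])-!@[#7!D1])",
  "&!$([#7!D1]-!@[CD3]=[N+])]-!@[!$(*#*)&!D1&!$(C(F)(F)F)",
  "&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])]"
)

# structural alerts (unwanted-functionality filters); each counts once when
# matched at least once
.QED_ALERT_SMARTS <- c(
  "*1[O,S,N]*1", "[S,C](=[O,S])[F,Br,Cl,I]", "[CX4][Cl,Br,I]",
  "[#6]S(=O)(=O)O[#6]", "[$([CH1]),$(CC)]#CC(=O)[#6]",
  "[$([CH1]),$(CC)]#CC(=O)O[#6]", "n[OH1]",
  "[$([CH1]),$(CC)]#CS(=O)(=O)[#6]", "C=C(C=O)C=O", "n1c([F,Cl,Br,I])cccc1",
  "[CH1]=O", "[#8][#8]", "[C;!R]=[N;!R]", "[N;!R]=[N;!R]", "[#6](=O)[#6]=O",
  "[#16][#16]", "[#7][NH2]", "C(=O)N[NH2]", "[#6]=S",
  "[$([CH2]),$([CH1][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH1][CX4]),$(C([CX4])[CX4])]",
  "C1(=[O,N])C=CC(=[O,N])C=C1", "C1(=[O,N])C(=[O,N])C=CC=C1",
  "a12aa3a(aa1aaaa2)aaaa3", "a12a(a3a(aa1)aaaa3)aaaa2",
  "a1aa2a3a(a1)A=AA=A3=AA=A2", "c1cc([NH2])ccc1",
  "[#80,#26,#33,#51,#30,#34,se,#52,B,#14,#11,#20,#32,#47,#12,#19,#56,#38,#4,#22,#42,#25,#44,#46,#28,#29,#79,#48,#13,#31,#50,#45,#81,#83,#41,#3,#82,#72,#67]",
  "I", "OS(=O)(=O)[O-]", "[N+](=O)[O-]", "C(=O)N[OH1]", "C1NC(=O)NC1=O",
  "[SH1]", "[S-]", "c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "[CR1]1[CR1][CR1][CR1][CR1][CR1][CR1]1",
  "[CR1]1[CR1][CR1]cc[CR1][CR1]1",
  "[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1",
  "[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1", "C#C",
  "[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]",
  "[$([N+R]),$([n+R]),$([N+]=C)][O-]", "[#6]=N[OH1]", "[#6]=NOC=O",
  "[#6](=O)[CX4,CR0X3,O][#6]=O", "c1ccc2c(c1)ccc(=O)o2",
  "[O+,o+,S+,s+]", "N=C=O", "[NX3,NX4][F,Cl,Br,I]", "c1ccccc1OC(=O)[#6]",
  "[CR0]=[CR0][CR0]=[CR0]", "[C+,c+,C-,c-]", "N=[N+]=[N-]",
  "C12C(NC(N1)=O)CSC2", "c1c([OH1])c([OH1,NH2,NH1])ccc1", "P",
  "[N,O,S]C#N", "C=C=O", "[#14][F,Cl,Br,I]", "[SX2]O",
  "[#14R0,CR0](c1ccccc1)(c1ccccc1)c1ccccc1",
  "O1CCCCC1OC1CCC2CCCCC2C1", "N=[CR0][N,n,O,S]",
  "[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]1[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]1",
  "C=[C;!R]C#N",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1[N+0X3R0,nX3R0]",
  "[OH1]c1ccc([OH1,NH2,NH1])cc1", "c1ccccc1OC(=O)O", "[SX2H0]N",
  "c12ccccc1SC(S)=N2", "c12ccccc1SC(=S)N2", "c1nnnn1C=O",
  "s1c(S)nnc1NC=O", "S1C=CSC1=S", "C(=O)Onnn", "OS(=O)(=O)C(F)(F)F",
  "N#CC[OH1]", "N#CC=O", "S(=O)(=O)C#N", "N[CH2]C#N", "C1(=O)NCC1",
  "S(=O)(=O)[O-,OH1]", "NC[F,Cl,Br,I]", "C=[C;!R]O", "[NX2+0]=[O+0]",
  "[OR0,NR0][OR0,NR0]", "[CX2R0][NX3R0]", "c1ccccc1[C;!R]=[C;!R]c1ccccc1",
  "[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]",
  "[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]",
  "*=[N+]=*", "[SX3](=O)[O-,OH1]", "N#N",
  "[R0;D2][R0;D2][R0;D2][R0;D2]", "[cR,CR]~C(=O)NC(=O)~[cR,CR]",
  "C=!@CC=[O,S]", "[#6,#8,#16][#6](=O)O[#6]", "c[CR0](=[O,S])[#6]",
  "c[SX2][C;!R]", "C=C=C", "c1nc([F,Cl,Br,I,S])ncc1",
  "c1ncnc([F,Cl,Br,I,S])c1", "c1ncc2c(n1)nc(n2)[F,Cl,Br,I]",
  "[#6]S(=O)(=O)c1ccc(cc1)F",
  "[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]"
)
# dot-disconnected alerts OpenBabel SMARTS cannot express; counted as
# threshold rules instead: >= 4 fluorines, >= 3 ester groups
.QED_ALERT_COUNT_RULES <- list(
  list(pattern = "F", min = 4L),
  list(pattern = "C(=O)O[#6]", min = 3L)
)

.with_obmol <- function(smiles, f) {
  ChemmineOB::forEachMol("SMILES", smiles, f)[[1L]]
}

#' QED descriptor profile of a molecule
#'
#' The eight descriptors feeding [qed()]: molecular weight, ALOGP, H-bond
#' acceptors/donors, topological polar surface area, rotatable bonds,
#' aromatic rings and structural-alert count.
#'
#' @param smiles a single SMILES string; must parse.
#' @return named list of the eight descriptor values.
#' @export
qed_properties <- function(smiles) {
  # descriptors are computed on the canonical (aromatized) form so that ring
  # perception does not depend on how the input was written
  can <- canonicalize(smiles)
  if (is.na(can)) stop("invalid SMILES '", smiles, "'")
  g <- smi_parse(can)
  if (!g$ok) stop("invalid SMILES '", smiles, "': ", g$error)
  ob <- .with_obmol(can, function(m) {
    p <- ChemmineOB::prop_OB(m)
    hba <- sum(vapply(.QED_ACCEPTOR_SMARTS, function(pt)
      ChemmineOB::smartsSearch_OB(list(m), pt), 1))
    hbd <- ChemmineOB::smartsSearch_OB(list(m), .QED_HBD_SMARTS)
    rotb <- ChemmineOB::smartsSearch_OB(list(m), .QED_ROTB_SMARTS)
    alerts <- sum(vapply(.QED_ALERT_SMARTS, function(pt)
      ChemmineOB::smartsSearch_OB(list(m), pt) > 0, TRUE))
    alerts <- alerts + sum(vapply(.QED_ALERT_COUNT_RULES, function(r)
      ChemmineOB::smartsSearch_OB(list(m), r$pattern) >= r$min, TRUE))
    list(logp = p$logP, psa = p$TPSA, hba = hba, hbd = hbd,
         rotb = rotb, alerts = alerts)
  })
  list(MW = smi_mw(g), ALOGP = ob$logp, HBA = as.integer(ob$hba),
       HBD = as.integer(ob$hbd), PSA = ob$psa, ROTB = as.integer(ob$rotb),
       AROM = smi_n_aromatic_rings(g), ALERTS = as.integer(ob$alerts))
}

.ads <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]
  dmax <- p[7]
  v <- a + b / (1 + exp(-(x - cc + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))
  v / dmax
}

#' QED drug-likeness score
#'
#' Weighted geometric mean of the eight descriptor desirabilities; values lie
#' in (0, 1), higher is more drug-like. Invalid SMILES score 0.
#'
#' @param smiles a single SMILES string.
#' @return QED value in `[0, 1]`.
#' @examples
#' \donttest{
#' qed("CC1=C(CCN2CCC(CC2)c2noc3cc(F)ccc23)C(=O)N2CCCCC2=N1")  # risperidone
#' }
#' @export
qed <- function(smiles) {
  if (is.na(canonicalize(smiles))) return(0)
  p <- qed_properties(smiles)
  d <- vapply(names(.QED_WEIGHTS), function(nm)
    .ads(p[[nm]], .QED_ADS[[nm]]), 1)
  w <- .QED_WEIGHTS
  unname(exp(sum(w * log(pmax(d, 1e-12))) / sum(w)))
}

#' Molecular weight
#'
#' Average-mass molecular weight including implicit hydrogens.
#'
#' @param smiles a single SMILES string; must parse.
#' @return mass in Dalton.
#' @export
molecular_weight <- function(smiles) {
  g <- smi_parse(smiles)
  if (!g$ok) stop("invalid SMILES '", smiles, "': ", g$error)
  smi_mw(g)
}

#' Reference molecules used by the worked examples
#'
#' Standard structures (as SMILES) of the two marketed dopamine-receptor
#' drugs used as similarity target and drug-likeness reference.
#'
#' @return named character vector with entries `risperidone` and
#'   `aripiprazole`.
#' @export
ref_molecules <- function() {
  c(
    risperidone = "CC1=C(CCN2CCC(CC2)c2noc3cc(F)ccc23)C(=O)N2CCCCC2=N1",
    aripiprazole = "O=C1CCc2ccc(OCCCCN3CCN(c4cccc(Cl)c4Cl)CC3)cc2N1"
  )
}
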