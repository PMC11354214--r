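# Idealized side-chain internal-coordinate templates (heavy atoms).
# Generated once from CCD ideal residue coordinates; torsions on a chi
# axis are stored as chi index + offset so rotamers can be substituted.
.sidechain_templates <- list(
  ALA = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5294, ang=109.4474, chi=NA_integer_, tor=120.0096)
  ),
  ARG = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5363, ang=111.9794, chi=NA_integer_, tor=123.3008),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5371, ang=114.5356, chi=1L, tor=0.0000),
    list(atom="CD", el="C", A="CA", B="CB", C="CG", b=1.5273, ang=112.4170, chi=2L, tor=0.0000),
    list(atom="NE", el="N", A="CB", B="CG", C="CD", b=1.4435, ang=111.0161, chi=3L, tor=0.0000),
    list(atom="CZ", el="C", A="CG", B="CD", C="NE", b=1.4058, ang=123.0046, chi=4L, tor=0.0000),
    list(atom="NH1", el="N", A="CD", B="NE", C="CZ", b=1.3905, ang=120.9962, chi=NA_integer_, tor=179.9864),
    list(atom="NH2", el="N", A="CD", B="NE", C="CZ", b=1.3912, ang=119.8148, chi=NA_integer_, tor=-0.0124)
  ),
  ASN = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5309, ang=109.4556, chi=NA_integer_, tor=119.9950),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5066, ang=109.4843, chi=1L, tor=0.0000),
    list(atom="OD1", el="O", A="CA", B="CB", C="CG", b=1.2133, ang=119.9743, chi=2L, tor=0.0000),
    list(atom="ND2", el="N", A="CA", B="CB", C="CG", b=1.3476, ang=120.0120, chi=2L, tor=-179.9262)
  ),
  ASP = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5301, ang=109.4716, chi=NA_integer_, tor=120.0162),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5075, ang=109.4630, chi=1L, tor=0.0000),
    list(atom="OD1", el="O", A="CA", B="CB", C="CG", b=1.2080, ang=119.9590, chi=2L, tor=0.0000),
    list(atom="OD2", el="O", A="CA", B="CB", C="CG", b=1.3415, ang=119.9993, chi=2L, tor=-179.9359)
  ),
  CYS = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5285, ang=109.5112, chi=NA_integer_, tor=120.0043),
    list(atom="SG", el="S", A="N", B="CA", C="CB", b=1.8141, ang=109.4981, chi=1L, tor=0.0000)
  ),
  GLN = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5288, ang=109.5405, chi=NA_integer_, tor=120.0165),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5284, ang=109.5344, chi=1L, tor=0.0000),
    list(atom="CD", el="C", A="CA", B="CB", C="CG", b=1.5066, ang=109.5426, chi=2L, tor=0.0000),
    list(atom="OE1", el="O", A="CB", B="CG", C="CD", b=1.2122, ang=119.9367, chi=3L, tor=0.0000),
    list(atom="NE2", el="N", A="CB", B="CG", C="CD", b=1.3471, ang=120.0933, chi=3L, tor=-179.9569)
  ),
  GLU = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5302, ang=109.4279, chi=NA_integer_, tor=119.9889),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5306, ang=109.4016, chi=1L, tor=0.0000),
    list(atom="CD", el="C", A="CA", B="CB", C="CG", b=1.5076, ang=109.4303, chi=2L, tor=0.0000),
    list(atom="OE1", el="O", A="CB", B="CG", C="CD", b=1.2084, ang=120.0030, chi=3L, tor=0.0000),
    list(atom="OE2", el="O", A="CB", B="CG", C="CD", b=1.3425, ang=119.9977, chi=3L, tor=-179.9373)
  ),
  GLY = list(

  ),
  HIS = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5337, ang=109.9372, chi=NA_integer_, tor=123.4614),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5100, ang=112.9791, chi=1L, tor=0.0000),
    list(atom="ND1", el="N", A="CA", B="CB", C="CG", b=1.3513, ang=120.3285, chi=2L, tor=0.0000),
    list(atom="CD2", el="C", A="CA", B="CB", C="CG", b=1.3376, ang=129.9283, chi=2L, tor=179.8457),
    list(atom="CE1", el="C", A="CB", B="CG", C="ND1", b=1.3369, ang=107.8621, chi=NA_integer_, tor=179.9049),
    list(atom="NE2", el="N", A="CB", B="CG", C="CD2", b=1.3739, ang=105.3318, chi=NA_integer_, tor=-179.8641)
  ),
  ILE = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5288, ang=109.5456, chi=NA_integer_, tor=120.0026),
    list(atom="CG1", el="C", A="N", B="CA", C="CB", b=1.5294, ang=109.5474, chi=1L, tor=0.0000),
    list(atom="CG2", el="C", A="N", B="CA", C="CB", b=1.5303, ang=109.4577, chi=1L, tor=-119.9719),
    list(atom="CD1", el="C", A="CA", B="CB", C="CG1", b=1.5288, ang=109.5474, chi=2L, tor=0.0000)
  ),
  LEU = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5286, ang=109.4932, chi=NA_integer_, tor=119.9257),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5303, ang=109.4950, chi=1L, tor=0.0000),
    list(atom="CD1", el="C", A="CA", B="CB", C="CG", b=1.5300, ang=109.5000, chi=2L, tor=0.0000),
    list(atom="CD2", el="C", A="CA", B="CB", C="CG", b=1.5285, ang=109.5008, chi=2L, tor=120.0918)
  ),
  LYS = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5300, ang=109.4542, chi=NA_integer_, tor=119.9661),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5307, ang=109.4176, chi=1L, tor=0.0000),
    list(atom="CD", el="C", A="CA", B="CB", C="CG", b=1.5308, ang=109.4405, chi=2L, tor=0.0000),
    list(atom="CE", el="C", A="CB", B="CG", C="CD", b=1.5291, ang=109.4647, chi=3L, tor=0.0000),
    list(atom="NZ", el="N", A="CG", B="CD", C="CE", b=1.4694, ang=109.5004, chi=4L, tor=0.0000)
  ),
  MET = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5294, ang=109.5428, chi=NA_integer_, tor=119.9660),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5284, ang=109.5449, chi=1L, tor=0.0000),
    list(atom="SD", el="S", A="CA", B="CB", C="CG", b=1.8137, ang=109.5064, chi=2L, tor=0.0000),
    list(atom="CE", el="C", A="CB", B="CG", C="SD", b=1.8135, ang=100.0339, chi=3L, tor=0.0000)
  ),
  PHE = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5289, ang=109.5362, chi=NA_integer_, tor=120.0557),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5052, ang=109.5165, chi=1L, tor=0.0000),
    list(atom="CD1", el="C", A="CA", B="CB", C="CG", b=1.3817, ang=120.0585, chi=2L, tor=0.0000),
    list(atom="CD2", el="C", A="CA", B="CB", C="CG", b=1.3832, ang=120.0047, chi=2L, tor=179.7575),
    list(atom="CE1", el="C", A="CB", B="CG", C="CD1", b=1.3820, ang=120.0292, chi=NA_integer_, tor=179.9942),
    list(atom="CE2", el="C", A="CB", B="CG", C="CD2", b=1.3819, ang=119.9770, chi=NA_integer_, tor=179.8391),
    list(atom="CZ", el="C", A="CG", B="CD1", C="CE1", b=1.3806, ang=120.0469, chi=NA_integer_, tor=-0.0485)
  ),
  PRO = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5434, ang=110.4143, chi=NA_integer_, tor=115.3135),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5426, ang=105.0594, chi=1L, tor=0.0000),
    list(atom="CD", el="C", A="CA", B="CB", C="CG", b=1.5437, ang=105.0631, chi=2L, tor=0.0000)
  ),
  SER = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5287, ang=109.5059, chi=NA_integer_, tor=119.9991),
    list(atom="OG", el="O", A="N", B="CA", C="CB", b=1.4283, ang=109.5115, chi=1L, tor=0.0000)
  ),
  THR = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5290, ang=109.5324, chi=NA_integer_, tor=119.9261),
    list(atom="OG1", el="O", A="N", B="CA", C="CB", b=1.4280, ang=109.5053, chi=1L, tor=0.0000),
    list(atom="CG2", el="C", A="N", B="CA", C="CB", b=1.5301, ang=109.5255, chi=1L, tor=-120.0308)
  ),
  TRP = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5286, ang=109.4878, chi=NA_integer_, tor=120.0469),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5067, ang=109.4419, chi=1L, tor=0.0000),
    list(atom="CD1", el="C", A="CA", B="CB", C="CG", b=1.3426, ang=126.4957, chi=2L, tor=0.0000),
    list(atom="CD2", el="C", A="CA", B="CB", C="CG", b=1.4639, ang=126.5119, chi=2L, tor=179.6215),
    list(atom="NE1", el="N", A="CB", B="CG", C="CD1", b=1.3686, ang=109.9318, chi=NA_integer_, tor=179.9435),
    list(atom="CE2", el="C", A="CG", B="CD1", C="NE1", b=1.3768, ang=109.8503, chi=NA_integer_, tor=-0.0618),
    list(atom="CE3", el="C", A="CD1", B="CG", C="CD2", b=1.3961, ang=134.0470, chi=NA_integer_, tor=-179.5343),
    list(atom="CZ2", el="C", A="CG", B="CD2", C="CE2", b=1.3906, ang=119.3458, chi=NA_integer_, tor=-179.8255),
    list(atom="CZ3", el="C", A="CG", B="CD2", C="CE3", b=1.3659, ang=119.7952, chi=NA_integer_, tor=179.6391),
    list(atom="CH2", el="C", A="CD2", B="CE2", C="CZ2", b=1.3773, ang=119.8063, chi=NA_integer_, tor=0.2212)
  ),
  TYR = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5287, ang=109.5062, chi=NA_integer_, tor=120.0190),
    list(atom="CG", el="C", A="N", B="CA", C="CB", b=1.5062, ang=109.4975, chi=1L, tor=0.0000),
    list(atom="CD1", el="C", A="CA", B="CB", C="CG", b=1.3823, ang=119.9470, chi=2L, tor=0.0000),
    list(atom="CD2", el="C", A="CA", B="CB", C="CG", b=1.3830, ang=119.9427, chi=2L, tor=179.6919),
    list(atom="CE1", el="C", A="CB", B="CG", C="CD1", b=1.3810, ang=120.0729, chi=NA_integer_, tor=-179.9763),
    list(atom="CE2", el="C", A="CB", B="CG", C="CD2", b=1.3809, ang=120.0203, chi=NA_integer_, tor=179.7745),
    list(atom="CZ", el="C", A="CG", B="CD1", C="CE1", b=1.3867, ang=119.9781, chi=NA_integer_, tor=-0.1021),
    list(atom="OH", el="O", A="CD1", B="CE1", C="CZ", b=1.3582, ang=120.1300, chi=NA_integer_, tor=-179.9660)
  ),
  VAL = list(
    list(atom="CB", el="C", A="N", B="C", C="CA", b=1.5287, ang=109.4913, chi=NA_integer_, tor=119.9755),
    list(atom="CG1", el="C", A="N", B="CA", C="CB", b=1.5299, ang=109.5086, chi=1L, tor=0.0000),
    list(atom="CG2", el="C", A="N", B="CA", C="CB", b=1.5292, ang=109.4895, chi=1L, tor=120.0257)
  )
)

.n_chi <- c(ALA=0L, ARG=4L, ASN=2L, ASP=2L, CYS=1L, GLN=3L, GLU=3L, GLY=0L,
            HIS=2L, ILE=2L, LEU=2L, LYS=4L, MET=3L, PHE=2L, PRO=2L, SER=1L,
            THR=1L, TRP=2L, TYR=2L, VAL=1L)
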