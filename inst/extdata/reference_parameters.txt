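# proxtub model parameters (MKSA; concentrations in mM = mol/m^3)
temperature_K = 310
perm.am.Na_m_s = 3e-10
perm.lm.K_m_s = 1.5e-06
perm.lm.Cl_m_s = 5.9999999999999997e-07
perm.sm.K_m_s = 9.9999999999999995e-08
perm.sm.Cl_m_s = 3e-09
perm.tj.Na_m_s = 4.3935529470338934e-09
perm.tj.K_m_s = 4.3935529470338934e-09
perm.tj.Cl_m_s = 5.0000000000000004e-06
perm.tj.Gluc_m_s = 3.9999999999999998e-07
perm.ibm.Na_m_s = 2.4999999999999999e-07
perm.ibm.K_m_s = 2.4999999999999999e-07
perm.ibm.Cl_m_s = 2.4999999999999999e-07
perm.ibm.Gluc_m_s = 5.0000000000000002e-05
lp.am_m_s_Pa = 3.5000000000000002e-11
lp.lm_m_s_Pa = 1.3642938309870378e-08
lp.sm_m_s_Pa = 1e-10
lp.tj_m_s_Pa = 1.9999999999999999e-11
lp.ibm_m_s_Pa = 6.5095294983348722e-08
sigma.tj.Na = 0.69999999999999996
sigma.tj.K = 0.69999999999999996
sigma.tj.Cl = 0.45000000000000001
sigma.tj.Gluc = 0.80000000000000004
sigma.ibm.Na = 0.029999999999999999
sigma.ibm.K = 0.029999999999999999
sigma.ibm.Cl = 0.029999999999999999
sigma.ibm.Gluc = 0.029999999999999999
pump.Ppump_mol_s_V_m2 = 0.00059999999999999995
pump.Epump_V = 0.20037588002794279
pump.KNa_mM = 3.3999999999999999
pump.KK_mM = 0.75
sglt1.Pmax_m_s = 1.0930162194599636e-10
sglt1.Km_mM = 1
sglt1.nW = 264
glut1.Jmax_mol_m2_s = 7.7757736369474085e-05
glut1.K_mM = 20
glut1.fLm = 0.95697944863950757
nak2cl.kAm_mol_m2_s_mM4 = 1.3e-13
nak2cl.kSm_mol_m2_s_mM4 = 0
geometry.muAm_per_Pa = 0.00080000000000000004
geometry.muLm_per_Pa = 0.0016000000000000001
geometry.muSm_per_Pa = 0.00080000000000000004
geometry.volLisRef_m3_m2 = 3.1135058779942123e-07
geometry.DcMA_mol_m2 = 0.0013936279682246265
geometry.zA = -0.94999999999999996
geometry.volCRef_m3_m2 = 1.0000000000000001e-05
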