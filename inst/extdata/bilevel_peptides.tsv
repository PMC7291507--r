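accession	peptide	site_labels	cond_low	cond_opt	cond_high	precursor_ppm	product_ppm	missed_cleavages
SPLC1_S204380	TGQGKGyVYNSLLLAIGPEGGWtTPEVEEAINRR	Y192y T208t	1	0	0	20	50	2
SPLC1_S204380	TGQGKGyVYNSLLLAIGPEGGWTtPEVEEAINRR	Y192y T209t	1	0	0	20	50	2
SPLC1_S204380	tGQGKGyVYNSLLLAIGPEGGWTTPEVEEAINRR	T186t Y192y	1	0	0	20	50	2
SPLC1_S204380	TGQGKGYVYNSLLLAIGPEGGWttPEVEEAINRR	T208t T209t	1	1	1	20	50	2
SPLC1_S204380	GYVYNSLLLAIGPEGGWTTPEVEEAINRRFQPVSLGsR	S227s	1	0	0	20	50	2
SPLC1_S101160	SITNTVLEtGNAILTSDAHVDER	T215t	1	1	0	20	50	0
SPLC1_S101160	SITNTVLETGNAILTsDAHVDER	S222s	1	0	0	20	50	0
SPLC1_S208580	LWQSQNLPVIEMRVGIFtGPIVAGSLGsR	T556t S566s	1	0	0	20	50	1
SPLC1_S082160	VLEYAVKAARALNCEIAPYsK	S82s	1	0	0	20	50	2
SPLC1_S082160	BIGItRLHMEEDAGKLVHGGsDR	T132t S148s	1	0	0	20	50	2
SPLC1_S082160	BLVHGGsDRLAGSTYsMVDFNR	S148s S157s	1	0	0	20	50	1
SPLC1_S082160	BLVHGGSDRLAGstYSMVDFNR	S154s T155t	1	0	0	20	50	1
SPLC1_S082160	BLHMEEDAGKLVHGGSDRLAGStySMVDFNR	T155t Y156y	1	0	0	20	50	2
SPLC1_S082160	BRIVRYLGVsDGNMQEGSLR	S200s	1	1	1	20	50	2
SPLC1_S082160	BYLGVsDGNMQEGSLR	S200s	1	0	0	20	50	0
SPLC1_S082160	BCDVNISVRPVGQKEFGtK	T227t	1	0	0	20	50	1
SPLC1_S082160	BVLTDDRtVAQYFEATVAAGADtK	T342t T357t	1	0	0	20	50	1
SPLC1_S102760	ALStRNDDPLHACRPFDVGR	T214t	1	0	0	20	50	1
SPLC1_S208940	LAEEIVFGEEEVTTGAsNDLQQVTRVAR	S486s	1	0	0	20	50	1
SPLC1_S208940	LAEEIVFGEEEVTTGASNDLQQVtRVAR	T493t	1	0	0	20	50	1
SPLC1_S034010	ALFGNHRTNsDIDNLAGACLDALTLQGAGVLMDDR	S231s	1	0	0	20	50	1
SPLC1_S034010	ALFGNHRTNSDIDNLAGACLDALtLQGAGVLMDDR	T245t	1	0	0	20	50	1
SPLC1_S205200	MSETLQTQLYEIAQFANtLVR	T18t	1	1	0	20	50	0
SPLC1_S540320	LRHSAsHDSLTDLWNR	S755s	1	0	0	20	50	1
SPLC1_S540320	LtDSVDsHILARLGGDEFTILLENIRDIQEAIDVAER	T821t S826s	1	0	0	20	50	2
SPLC1_S540320	LTDsVDsHILARLGGDEFTILLENIRDIQEAIDVAER	S823s S826s	1	0	0	20	50	2
SPLC1_S270810	AILDLAFSAISQEIEsGQPVVVRGLGK	S38s	1	0	0	20	50	1
SPLC1_S430280	sVQDIGGELLVVSQFTLYGDCR	S68s	1	1	0	20	50	0
SPLC1_S430280	SVQDIGGELLVVsQFTLYGDCR	S80s	1	0	0	20	50	0
SPLC1_S430280	SVQDIGGELLVVSQFTLyGDCR	Y85y	1	1	0	20	50	0
SPLC1_S270380	tIVYKGMVRSAVLGEFYR	T234t	1	1	0	20	50	2
SPLC1_S270380	TIVyKGMVRSAVLGEFYR	Y237y	1	1	1	20	50	2
SPLC1_S082010	LVHAPSSSSIFHItKLMSR	T206t	1	0	0	20	50	1
SPLC1_S082010	LVHAPSSSSIFHITKLMsR	S210s	1	1	0	20	50	1
SPLC1_S230960	IGLVSAPPEVFLKtPsEMDEATQK	T320t S322s	1	1	1	20	50	1
SPLC1_S230960	IGLVSAPPEVFLKTPsEMDEAtQK	S322s T328t	1	0	0	20	50	1
SPLC1_S230960	IVtYLQSsQQELISVNR	T215t S220s	1	0	0	20	50	0
SPLC1_S230960	IVTYLQssQQELISVNR	S219s S220s	1	1	0	20	50	0
SPLC1_S040030	BLNsAVIVGDLETDNDAQRLR	S129s	1	0	0	20	50	1
SPLC1_S260960	EDPADALVVHENHRDKQLDtLPPGAVVGTSSLR	T127t	1	0	0	20	50	2
SPLC1_S051730	FNGDGTLVWAQSIGGSDLDSGNGIAVDDAGNVYATGsFSSR	S285s	1	0	0	20	50	0
SPLC1_S051730	FNGDGTLVWAQSIGGSDLDSGNGIAVDDAGNVYATGSFSsR	S288s	1	0	0	20	50	0
SPLC1_S130380	KYSIADMDsTSGDLAVETYEIVAEMITKEVALGGQVASMR	S149s	1	1	0	20	50	2
SPLC1_S130380	KYSIADMDStSGDLAVETYEIVAEMITKEVALGGQVASMR	T150t	1	0	0	20	50	2
SPLC1_S130380	KYSIADMDSTSGDLAVETYEIVAEMItKEVALGGQVASMR	T167t	1	1	1	20	50	2
SPLC1_S171520	FIPAFGSAIAASWAFAYTGALGEATCVyFGDLMGGK	Y398y	1	1	1	20	50	0
SPLC1_S171520	FIPAFGsAIAASWAFAYTGALGEATCVYFGDLMGGK	S377s	1	0	0	20	50	0
SPLC1_S202870	IWTFEQVQGILyVVVPIRMtVIR	Y56y T64t	1	0	0	20	50	1
SPLC1_S202870	LDMGGLLVyAPVAPTPECIRLVNELVAEYGEVR	Y76y	1	1	0	20	50	1
SPLC1_S202870	LDMGGLLVYAPVAPtPECIRLVNELVAEYGEVR	T82t	1	0	0	20	50	1
SPLC1_S202870	LDMGGLLVYAPVAPTPECIRLVNELVAEyGEVR	Y96y	1	0	0	20	50	1
SPLC1_S120070	QLVDLTDAKIVyPITFEERK	Y36y	1	1	1	20	50	2
SPLC1_S120070	QLVDLtDAKIVYPITFEERK	T30t	1	0	0	20	50	2
SPLC1_S510820	LGVTVDIIADLHPINPFNFVMESYAERyPFIYEEQLGR	Y102y	1	0	0	20	50	1
SPLC1_S510820	LGVTVDIIADLHPINPFNFVMESYAERYPFIyEEQLGR	Y106y	1	0	0	20	50	1
SPLC1_S205080	GGVEtVRKSLYQVITEVYGLLEK	T27t	1	0	0	20	50	2
SPLC1_S060060	MLRLEHISKIYPtGtILK	T13t T15t	1	1	0	20	50	2
SPLC1_S060060	IIAGEVEPTSGEVIKPSSLHIAYLTQEFEVDPARtVREEFWR	T80t	1	1	0	20	50	2
SPLC1_S060060	IIAGEVEPTSGEVIKPSSLHIAYLtQEFEVDPARTVREEFWR	T70t	1	0	0	20	50	2
SPLC1_S207550	IVSLSSIAGAITIAALMIItGQPLPYQIFAIAAGtYVIWRHR	T180t T195t	1	1	0	20	50	1
SPLC1_S207550	IVSLSSIAGAITIAALMIItGQPLPyQIFAIAAGTYVIWRHR	T180t Y186y	1	1	0	20	50	1
SPLC1_S410530	QVIAAQLPDGsALVEFVR	S61s	0	0	0	20	50	0
SPLC1_S542340	VVLVtGIAGFIGSAVARLLISKNQK	T13t	1	0	0	20	50	2
SPLC1_S542340	LASENYMKIysHQYNISSVALR	Y163y S164s	1	0	0	20	50	1
SPLC1_S542340	LASENYMKIYsHQyNISSVALR	S164s Y167y	1	1	0	20	50	1
SPLC1_S201490	LsGRTFFHRWQLAEALAEESESWQFQPPITR	S445s	1	0	0	20	50	2
SPLC1_S201490	LSGRTFFHRWQLAEALAEESESWQFQPPItR	T473t	1	0	0	20	50	2
SPLC1_S240360	SAVNIPGLYPDALEQLKPYLQLAETLGNLVsQLVGGR	S353s	1	0	0	20	50	0
SPLC1_S082540	VTACVPSQTRIRtQR	T18t	1	0	0	20	50	2
SPLC1_S203810	LQAVRyKQsFDK	Y606y S609s	1	1	1	20	50	2
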